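## Readers and writers for the plain-text interchange formats: species trait
## tables (CSV), occurrence points (CSV), the equal-area shelf grid (GeoJSON),
## fossil stratigraphic ranges and stage scales (CSV), and newick trees.

.feeding_levels    <- c("suspension", "deposit", "chemosymbiotic", "carnivore", "other")
.attachment_levels <- c("attached", "unattached")
.mobility_levels   <- c("mobile", "immobile")
.position_levels   <- c("infaunal", "epifaunal")

#' Canonical species-table column names and header aliases
#'
#' Species tables use the internal header
#' `species_id, family, exploited, in_fao, size_mm, min_bathy_m, gra_km2,
#' tr_c, feeding, attachment, mobility, position, qhat, peril`.
#' Published supplementary files often carry different headers; supply an
#' alias table (named character vector, `c(external = "internal")`) to map
#' them on read.
#'
#' @return character vector of canonical column names.
#' @export
species_table_columns <- function() {
  c("species_id", "family", "exploited", "in_fao", "size_mm", "min_bathy_m",
    "gra_km2", "tr_c", "feeding", "attachment", "mobility", "position",
    "qhat", "peril")
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Read a species trait table
#'
#' Reads a delimited species trait table (one row per species). Missing
#' values must be empty fields or `NA`, never sentinel numbers: a minimum
#' bathymetry of 0 m is a legal intertidal value. Rows whose categorical
#' traits fall outside the closed vocabularies (feeding: suspension, deposit,
#' chemosymbiotic, carnivore, other; attachment: attached/unattached;
#' mobility: mobile/immobile; position: infaunal/epifaunal) are dropped with
#' a message naming the offending value.
#'
#' @param path path to a CSV file with a header row.
#' @param aliases optional named character vector mapping external header
#'   names to the canonical names of [species_table_columns()].
#' @return a `data.frame` with the canonical columns; dropped rows are
#'   reported via `message()` and recorded in the `"rejected"` attribute.
#' @export
read_species_table <- function(path, aliases = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!is.null(aliases)) {
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- unname(aliases[names(raw)[hit]])
  }
  need <- c("species_id", "family", "exploited")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("species table is missing required column(s): ", paste(miss, collapse = ", "))
  for (col in setdiff(species_table_columns(), names(raw))) raw[[col]] <- NA
  raw <- raw[species_table_columns()]

  if (anyDuplicated(raw$species_id))
    stop("duplicate species_id: ",
         paste(unique(raw$species_id[duplicated(raw$species_id)]), collapse = ", "))

  raw$exploited <- .as_flag(raw$exploited)
  raw$in_fao <- .as_flag(raw$in_fao)
  raw$in_fao[is.na(raw$in_fao)] <- FALSE

  vocab <- list(feeding = .feeding_levels, attachment = .attachment_levels,
                mobility = .mobility_levels, position = .position_levels)
  bad <- rep(FALSE, nrow(raw))
  reasons <- character(0)
  for (col in names(vocab)) {
    v <- tolower(trimws(as.character(raw[[col]])))
    v[v == ""] <- NA
    raw[[col]] <- v
    off <- !is.na(v) & !(v %in% vocab[[col]])
    if (any(off)) {
      reasons <- c(reasons, sprintf("%s: unknown %s '%s'",
                                    raw$species_id[off], col, v[off]))
      bad <- bad | off
    }
  }
  if (any(bad)) {
    message("read_species_table: rejected ", sum(bad), " row(s): ",
            paste(reasons, collapse = "; "))
  }
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- raw$species_id[bad]
  out
}

#' Write a species trait table
#'
#' @param records data.frame of species records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read occurrence points or cell occupancies
#'
#' Accepts either point occurrences (`species_id, x_km, y_km`, coordinates in
#' an equal-area projection, km) or precomputed cell occupancies
#' (`species_id, cell_id`).
#'
#' @param path CSV path.
#' @return a data.frame with either (`species_id`, `x_km`, `y_km`) or
#'   (`species_id`, `cell_id`).
#' @export
read_occurrences <- function(path) {
  occ <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("x_km", "y_km") %in% names(occ))) {
    if (!all(is.finite(occ$x_km)) || !all(is.finite(occ$y_km)))
      stop("non-finite coordinates in ", path)
    occ[c("species_id", "x_km", "y_km")]
  } else if ("cell_id" %in% names(occ)) {
    occ[c("species_id", "cell_id")]
  } else {
    stop("occurrence file needs either x_km/y_km or cell_id columns")
  }
}

#' Split a point-occurrence table into per-species coordinate matrices
#'
#' @param occ data.frame from [read_occurrences()] with `x_km`/`y_km`.
#' @return named list of two-column matrices, one per species.
#' @export
occurrence_sets <- function(occ) {
  stopifnot(all(c("species_id", "x_km", "y_km") %in% names(occ)))
  lapply(split(occ[c("x_km", "y_km")], occ$species_id),
         function(d) as.matrix(d))
}

#' Read an equal-area shelf grid from GeoJSON
#'
#' Expects a FeatureCollection of square cells with properties `cell_id`,
#' `sst_mean`, and optionally `climate_zone` and `region`. Cell centroids are
#' recovered from the polygon coordinates; the cell side is inferred from the
#' first feature.
#'
#' @param path GeoJSON path.
#' @return a `shelf_grid`: data.frame with columns `cell_id`, `x`, `y`
#'   (centroid, km), `sst_mean`, `climate_zone`, `region`, plus a
#'   `cell_size` attribute (km).
#' @export
read_shelf_grid <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    pr <- f$properties
    data.frame(cell_id = as.character(pr$cell_id),
               x = mean(range(xs)), y = mean(range(ys)),
               sst_mean = if (is.null(pr$sst_mean)) NA_real_ else as.numeric(pr$sst_mean),
               climate_zone = if (is.null(pr$climate_zone)) NA_character_ else as.character(pr$climate_zone),
               region = if (is.null(pr$region)) NA_character_ else as.character(pr$region),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  if (anyDuplicated(grid$cell_id)) stop("duplicate cell_id in grid")
  ring1 <- gj$features[[1]]$geometry$coordinates[[1]]
  xs1 <- vapply(ring1, function(p) as.numeric(p[[1]]), numeric(1))
  attr(grid, "cell_size") <- diff(range(xs1))
  class(grid) <- c("shelf_grid", "data.frame")
  grid
}

.cell_feature <- function(x, y, half, props) {
  list(type = "Feature",
       geometry = list(type = "Polygon",
                       coordinates = list(list(
                         c(x - half, y - half), c(x + half, y - half),
                         c(x + half, y + half), c(x - half, y + half),
                         c(x - half, y - half)))),
       properties = props)
}

#' Write a shelf grid (optionally with extra per-cell columns) to GeoJSON
#'
#' @param grid a `shelf_grid` data.frame (columns `cell_id`, `x`, `y`, ...).
#' @param path output path.
#' @param extra optional data.frame of additional per-cell properties, keyed
#'   by a `cell_id` column (e.g. a vulnerability layer).
#' @return `path`, invisibly.
#' @export
write_shelf_grid <- function(grid, path, extra = NULL) {
  half <- attr(grid, "cell_size") / 2
  if (is.null(half) || !is.finite(half)) half <- 25
  if (!is.null(extra)) {
    grid <- merge(as.data.frame(grid), extra, by = "cell_id",
                  all.x = TRUE, sort = FALSE)
  }
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    props <- as.list(grid[i, setdiff(names(grid), c("x", "y")), drop = FALSE])
    .cell_feature(grid$x[i], grid$y[i], half, props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read fossil stratigraphic ranges
#'
#' @param path CSV with columns `genus, family, first_stage, last_stage`.
#' @param scale optional stage scale; when given, stage names are validated
#'   and first/last ordering checked.
#' @return data.frame of genus ranges.
#' @export
read_fossil_ranges <- function(path, scale = NULL) {
  rng <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("genus", "family", "first_stage", "last_stage")
  if (!all(need %in% names(rng)))
    stop("fossil range file needs columns: ", paste(need, collapse = ", "))
  if (!is.null(scale)) .validate_ranges(rng, scale)
  rng[need]
}

#' Read a stage scale
#'
#' @param path CSV with columns `name, base_age, top_age` (Ma), ordered old
#'   to young.
#' @return a validated stage-scale data.frame (see [stage_scale()]).
#' @export
read_stage_scale <- function(path) {
  sc <- read.csv(path, stringsAsFactors = FALSE)
  stage_scale(sc$name, sc$base_age, sc$top_age)
}

#' Read a time-scaled family tree from newick
#'
#' Wraps [ape::read.tree()] and checks that every edge has a branch length
#' and (by default) that the tree is ultrametric to within a relative
#' tolerance of its height.
#'
#' @param path newick file.
#' @param require_ultrametric warn (not error) if the tree is not ultrametric.
#' @param tol relative tolerance on tip depths.
#' @return an `ape::phylo` tree.
#' @export
read_family_tree <- function(path, require_ultrametric = TRUE, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree in ", path, " has missing branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (require_ultrametric && !ape::is.ultrametric(tree, tol = tol * max(ape::node.depth.edgelength(tree))))
    warning("tree is not ultrametric within tolerance")
  tree
}

#' Write a tree to newick
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
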