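## Biogeography on the equal-area shelf grid: per-cell richness and
## proportion layers, region assignment (climate band x coastline), and the
## vulnerability layer counting exploited species above a global or regional
## PERIL quantile threshold in each cell.

.occupancy_long <- function(occupancy) {
  stopifnot(is.list(occupancy), !is.null(names(occupancy)))
  n <- vapply(occupancy, length, integer(1))
  empty <- names(occupancy)[n == 0]
  if (length(empty))
    message("species with no occupied cells excluded: ",
            paste(empty, collapse = ", "))
  data.frame(species_id = rep(names(occupancy), n),
             cell_id = unlist(occupancy, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Per-cell species richness
#'
#' @param occupancy named list: species_id -> character vector of occupied
#'   cell ids.
#' @param species optional character vector restricting the count to a
#'   subset of species (e.g. the exploited ones).
#' @return data.frame `cell_id, n` with one row per occupied cell.
#' @export
richness_map <- function(occupancy, species = NULL) {
  long <- .occupancy_long(occupancy)
  if (!is.null(species)) long <- long[long$species_id %in% species, , drop = FALSE]
  if (!nrow(long)) return(data.frame(cell_id = character(0), n = integer(0)))
  tab <- table(long$cell_id)
  data.frame(cell_id = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-cell proportions from two aligned count layers
#'
#' @param numerator,denominator data.frames `cell_id, n` (e.g. from
#'   [richness_map()]). Numerator cells must be a subset of denominator
#'   cells.
#' @return data.frame `cell_id, n_num, n_den, prop`; cells with a zero or
#'   absent numerator get 0, cells with denominator 0 get `NA` (undefined).
#' @export
proportion_map <- function(numerator, denominator) {
  extra <- setdiff(numerator$cell_id[numerator$n > 0], denominator$cell_id)
  if (length(extra))
    stop("numerator has cells absent from denominator: ",
         paste(head(extra, 5), collapse = ", "))
  m <- merge(denominator, numerator, by = "cell_id", all.x = TRUE,
             suffixes = c("_den", "_num"))
  m$n_num <- ifelse(is.na(m$n_num), 0L, m$n_num)
  data.frame(cell_id = m$cell_id, n_num = m$n_num, n_den = m$n_den,
             prop = ifelse(m$n_den > 0, m$n_num / m$n_den, NA_real_),
             stringsAsFactors = FALSE)
}

#' Assign regions to grid cells
#'
#' The default scheme crosses latitudinal climate bands with an optional
#' per-cell coastline label: a cell's centroid `y` (km, equal-area
#' projection on a spherical datum, `y = R sin(lat)`) maps to tropical
#' (|lat| <= 23.44 deg), temperate (<= 66.56 deg) or polar. A `scheme`
#' data.frame (`cell_id, region`) overrides the default wherever it covers
#' a cell.
#'
#' @param grid a `shelf_grid`.
#' @param scheme optional data.frame `cell_id, region`.
#' @param coast optional per-cell coastline label, crossed with the climate
#'   band as `"<band> <coast>"`.
#' @return named character vector: cell_id -> region.
#' @export
assign_regions <- function(grid, scheme = NULL, coast = NULL) {
  R_earth <- 6371
  lat <- asin(pmin(1, pmax(-1, grid$y / R_earth))) * 180 / pi
  band <- ifelse(abs(lat) <= 23.44, "tropical",
                 ifelse(abs(lat) <= 66.56, "temperate", "polar"))
  region <- if (is.null(coast)) band else paste(band, coast)
  names(region) <- grid$cell_id
  if (!is.null(scheme)) {
    bad <- setdiff(scheme$cell_id, grid$cell_id)
    if (length(bad)) stop("scheme covers unknown cells: ",
                          paste(head(bad, 5), collapse = ", "))
    region[scheme$cell_id] <- scheme$region
  }
  region
}

#' Assign each species to a single region
#'
#' A species' region is the region containing the largest share of its
#' occupied cells; ties break alphabetically.
#'
#' @param occupancy named list species_id -> cell ids.
#' @param cell_regions named vector cell_id -> region (see
#'   [assign_regions()]).
#' @return named character vector species_id -> region.
#' @export
species_region <- function(occupancy, cell_regions) {
  vapply(occupancy, function(cells) {
    r <- cell_regions[cells]
    r <- r[!is.na(r)]
    if (!length(r)) return(NA_character_)
    tab <- sort(table(r), decreasing = TRUE)
    names(tab)[tab == max(tab)][order(names(tab)[tab == max(tab)])][1]
  }, character(1))
}

#' Per-cell vulnerability layer
#'
#' For every occupied grid cell, counts species, exploited species,
#' vulnerable species (PERIL strictly above the quantile threshold of the
#' full species pool — global scope — or of the species' own region's
#' pool), and vulnerable exploited species, plus the proportions mapped in
#' regional assessments: the share of exploited species in the cell, the
#' share of the cell's vulnerable species that are exploited, and the share
#' of the cell's exploited species that are vulnerable.
#'
#' @param records data.frame with `species_id`, `exploited`, and a `peril`
#'   score column (or pass a `"peril"` object's data via [peril_scores()]
#'   merged in).
#' @param occupancy named list species_id -> occupied cell ids.
#' @param quantile threshold quantile (0.5 = median, 0.8 = top 20%).
#' @param scope `"global"` or `"regional"`.
#' @param cell_regions named vector cell_id -> region; required for
#'   regional scope (species regions follow [species_region()]).
#' @return data.frame of class `"vulnerability_layer"`: `cell_id`,
#'   `n_species`, `n_exploited`, `n_vulnerable`, `n_vulnerable_exploited`,
#'   `prop_exploited`, `prop_exploited_among_vulnerable`,
#'   `prop_vulnerable_exploited` (undefined proportions are `NA`);
#'   attributes `threshold_scope`, `threshold_quantile`, `quantile_type`.
#' @export
vulnerability_layer <- function(records, occupancy, quantile = 0.5,
                                scope = c("global", "regional"),
                                cell_regions = NULL) {
  scope <- match.arg(scope)
  stopifnot(all(c("species_id", "exploited", "peril") %in% names(records)))
  scores <- setNames(records$peril, records$species_id)
  exploited <- setNames(as.logical(records$exploited), records$species_id)

  occupancy <- occupancy[names(occupancy) %in% records$species_id]
  if (scope == "regional") {
    if (is.null(cell_regions)) stop("regional scope requires cell_regions")
    sp_region <- species_region(occupancy, cell_regions)
    regions <- sp_region[names(scores)]
    vuln <- vulnerable(scores, quantile = quantile, scope = "regional",
                       regions = regions, reference = scores,
                       reference_regions = regions)
  } else {
    vuln <- vulnerable(scores, quantile = quantile, scope = "global")
  }
  names(vuln) <- names(scores)

  long <- .occupancy_long(occupancy)
  long$exploited <- exploited[long$species_id]
  long$vulnerable <- vuln[long$species_id]
  agg <- aggregate(
    cbind(n_species = 1L,
          n_exploited = as.integer(long$exploited),
          n_vulnerable = as.integer(long$vulnerable %in% TRUE),
          n_vulnerable_exploited = as.integer(long$vulnerable %in% TRUE & long$exploited)),
    by = list(cell_id = long$cell_id), FUN = sum)
  agg$prop_exploited <- agg$n_exploited / agg$n_species
  agg$prop_exploited_among_vulnerable <-
    ifelse(agg$n_vulnerable > 0, agg$n_vulnerable_exploited / agg$n_vulnerable, NA_real_)
  agg$prop_vulnerable_exploited <-
    ifelse(agg$n_exploited > 0, agg$n_vulnerable_exploited / agg$n_exploited, NA_real_)
  structure(agg, threshold_scope = scope, threshold_quantile = quantile,
            quantile_type = 7L,
            class = c("vulnerability_layer", "data.frame"))
}

#' Write a vulnerability layer with its rule metadata
#'
#' Writes the layer as GeoJSON cell properties (via [write_shelf_grid()])
#' plus a JSON metadata sidecar recording the threshold rule, quantile
#' convention and package version.
#'
#' @param layer a [vulnerability_layer()] result.
#' @param grid the `shelf_grid` the layer was computed on.
#' @param path output GeoJSON path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_vulnerability_layer <- function(layer, grid, path) {
  write_shelf_grid(grid, path, extra = as.data.frame(layer))
  meta <- list(threshold_scope = attr(layer, "threshold_scope"),
               threshold_quantile = attr(layer, "threshold_quantile"),
               quantile_type = attr(layer, "quantile_type"),
               package_version = as.character(packageVersion("perilscore")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
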