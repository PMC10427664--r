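## Trait assembly: shell size, convex-hull geographic range, grid occupancy,
## realized thermal range, minimum-bathymetry imputation. All geometry is in
## a projected equal-area plane with km units (Lambert cylindrical equal-area
## for real data); areas therefore come out in km2 directly.

#' Shell body size as the geometric mean of length and height
#'
#' @param length_mm shell length, anterior to posterior margin (mm).
#' @param height_mm shell height, dorsal to ventral margin (mm).
#' @return size in mm, `sqrt(length * height)`. Vectorized.
#' @export
#' @examples
#' body_size(100, 100)  # 100
#' body_size(4, 9)      # 6
body_size <- function(length_mm, height_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(height_mm)) ||
      any(length_mm <= 0) || any(height_mm <= 0))
    stop("length and height must be finite and positive")
  sqrt(length_mm * height_mm)
}

#' Area of the convex hull of projected points
#'
#' @param points a two-column matrix of (x, y) coordinates, km.
#' @return hull area in km2; 0 for degenerate input (a single point, two
#'   points, or a collinear set).
#' @export
convex_hull_area <- function(points) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("non-finite coordinate")
  points <- unique(points)
  if (nrow(points) < 3) return(0)
  h <- grDevices::chull(points)
  if (length(h) < 3) return(0)
  x <- points[h, 1]; y <- points[h, 2]
  # shoelace formula
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Geographic range area with the single-occurrence floor
#'
#' The convex-hull area of a species' occurrences, floored at `floor_km2`
#' (default 100 km2, a nominal 10 km x 10 km footprint for species known
#' from a single point). Degenerate hulls (one or two points, collinear
#' sets) also take the floor: a zero-area range is biologically meaningless
#' and would break the `1/ln r` term of the PERIL score. An `override`
#' (e.g. a documented limited range for a single-estuary endemic) is
#' returned as-is.
#'
#' @param points two-column matrix of projected occurrences (km).
#' @param floor_km2 minimum range area, km2.
#' @param override optional documented range area, km2.
#' @return range area in km2.
#' @export
geographic_range_area <- function(points, floor_km2 = 100, override = NULL) {
  if (!is.null(override)) {
    if (override < 0) stop("override range area must be nonnegative")
    return(override)
  }
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("at least one occurrence point required")
  max(convex_hull_area(points), floor_km2)
}

## Separating-axis test between a convex vertex set and an axis-aligned
## square. strict = TRUE tests interior intersection (shared boundaries do
## not count), used for positive-area hulls so a hull spanning a block of
## cells exactly claims only that block.
.sat_intersects <- function(verts, cx, cy, half, strict = TRUE) {
  sq <- cbind(c(cx - half, cx + half, cx + half, cx - half),
              c(cy - half, cy - half, cy + half, cy + half))
  axes <- list(c(1, 0), c(0, 1))
  n <- nrow(verts)
  if (n >= 2) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      e <- verts[j, ] - verts[i, ]
      if (all(e == 0)) next
      axes[[length(axes) + 1L]] <- c(-e[2], e[1])
    }
  }
  sep <- if (strict) function(a, b) a <= b else function(a, b) a < b
  for (ax in axes) {
    p1 <- verts %*% ax; p2 <- sq %*% ax
    if (sep(max(p1), min(p2)) || sep(max(p2), min(p1))) return(FALSE)
  }
  TRUE
}

#' Grid cells occupied by a species
#'
#' Intersects the convex hull of a species' point occurrences with the
#' equal-area grid. Cells intersected in their interior by a positive-area
#' hull are occupied; for degenerate hulls (single point, two points,
#' collinear occurrences) a cell is occupied when it contains a hull vertex
#' or the connecting segment (closed intersection).
#'
#' @param points two-column matrix of projected occurrences (km), or `NULL`
#'   when `cells` is given.
#' @param grid a `shelf_grid` (see [read_shelf_grid()] / [make_grid()]).
#' @param cells optional character vector of precomputed cell ids, passed
#'   through (after validation against the grid).
#' @return character vector of occupied `cell_id`s; empty with a warning if
#'   the species misses the grid entirely.
#' @export
occupied_cells <- function(points, grid, cells = NULL) {
  if (!is.null(cells)) {
    bad <- setdiff(cells, grid$cell_id)
    if (length(bad)) stop("cells not in grid: ", paste(bad, collapse = ", "))
    return(unique(as.character(cells)))
  }
  points <- unique(as.matrix(points))
  if (!all(is.finite(points))) stop("non-finite coordinate")
  half <- attr(grid, "cell_size") / 2
  if (is.null(half) || !is.finite(half)) stop("grid lacks a cell_size attribute")
  h <- if (nrow(points) >= 3) grDevices::chull(points) else seq_len(nrow(points))
  verts <- points[h, , drop = FALSE]
  area <- convex_hull_area(points)
  strict <- area > 0
  # bounding-box prefilter, then exact separating-axis test
  bb <- apply(verts, 2, range)
  cand <- which(grid$x + half >= bb[1, 1] & grid$x - half <= bb[2, 1] &
                grid$y + half >= bb[1, 2] & grid$y - half <= bb[2, 2])
  hit <- cand[vapply(cand, function(i)
    .sat_intersects(verts, grid$x[i], grid$y[i], half, strict = strict),
    logical(1))]
  if (!length(hit)) warning("species occurrences do not intersect the grid")
  grid$cell_id[hit]
}

#' Realized thermal range across occupied cells
#'
#' @param cells character vector of occupied cell ids.
#' @param grid a `shelf_grid` with an `sst_mean` column (deg C).
#' @return `max - min` of per-cell SST across the occupied cells (deg C);
#'   0 for a single cell. Cells with missing SST are excluded with a
#'   warning; if none remain, an error.
#' @export
thermal_range <- function(cells, grid) {
  if (!length(cells)) stop("no occupied cells")
  idx <- match(cells, grid$cell_id)
  if (anyNA(idx)) stop("cells not in grid: ",
                       paste(cells[is.na(idx)], collapse = ", "))
  sst <- grid$sst_mean[idx]
  if (anyNA(sst)) {
    warning(sum(is.na(sst)), " occupied cell(s) lack SST; excluded")
    sst <- sst[!is.na(sst)]
  }
  if (!length(sst)) stop("no occupied cell has SST")
  max(sst) - min(sst)
}

#' Impute minimum bathymetry from a habitat descriptor
#'
#' Species lacking numeric bathymetric data but described as "subtidal" or
#' "sublittoral" are assigned a minimum bathymetry of 5 m; "shallow water"
#' species 10 m. Imputed values are flagged so sensitivity analyses can
#' exclude them.
#'
#' @param descriptor character vector of habitat descriptors.
#' @return data.frame with columns `min_bathy_m` (NA when the descriptor is
#'   unrecognized) and `imputed` (logical).
#' @export
impute_min_bathymetry <- function(descriptor) {
  d <- tolower(trimws(descriptor))
  val <- ifelse(d %in% c("subtidal", "sublittoral"), 5,
                ifelse(d == "shallow water", 10, NA_real_))
  unknown <- is.na(val) & !is.na(d)
  if (any(unknown))
    message("impute_min_bathymetry: unrecognized descriptor(s): ",
            paste(unique(d[unknown]), collapse = ", "))
  data.frame(min_bathy_m = val, imputed = !is.na(val))
}
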