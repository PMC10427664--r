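## Synthetic data with known ground truth: birth-death family trees, fossil
## records simulated under known per-capita extinction rates, an equal-area
## shelf grid with a latitudinal SST gradient, species occupancy footprints
## whose convex hulls reproduce target range areas, and exploitation labels
## drawn from a logistic model in which exploited species are larger,
## shallower, wider-ranging and more eurythermal.

#' Simulation configuration
#'
#' Bundles the generator parameters with their defaults. The defaults
#' emulate the structure of the study system: ~13% of species exploited,
#' trait effects on the exploitation log-odds of +0.8 per SD of log shell
#' size, -0.5 per SD of log minimum bathymetry, +0.5 per SD of log
#' geographic range and +0.5 per SD of thermal range (plus +0.5 for
#' attached species), a family random-intercept SD of 1, and Cenozoic
#' genus extinction rates drawn around 0.15 per Myr.
#'
#' @param seed integer seed.
#' @param n_families,n_species counts.
#' @param nx,ny,cell_size grid dimensions (cells) and cell side (km).
#' @param sst_eq,sst_pole,sst_noise_sd SST at the equatorward and poleward
#'   grid edges and per-cell noise SD (deg C).
#' @param effects named log-odds-per-SD vector for the four continuous
#'   traits; `attachment_effect` the log-odds bonus for attached species.
#' @param intercept logistic intercept (log-odds).
#' @param ranef_sd family random-intercept SD.
#' @param p_iso fraction of wide-ranging species whose footprints follow
#'   isotherms (wide in x, one cell tall), emulating widespread species
#'   that are not eurythermal.
#' @param qhat_shape,qhat_rate gamma parameters for true per-family
#'   extinction rates (per Myr).
#' @param genera_per_family fossil genera per family.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_families = 30L, n_species = 1000L,
                       nx = 80L, ny = 60L, cell_size = 50,
                       sst_eq = 28, sst_pole = -2, sst_noise_sd = 0.5,
                       effects = c(size = 0.8, min_bathymetry = -0.5,
                                   geographic_range = 0.5, thermal_range = 0.5),
                       attachment_effect = 0.5,
                       intercept = -2.2, ranef_sd = 1,
                       p_iso = 0.25,
                       qhat_shape = 4, qhat_rate = 25,
                       genera_per_family = 40L) {
  stopifnot(n_families >= 3, n_species > 0, nx > 0, ny > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric birth-death family tree
#'
#' @param n_families number of tips (>= 3).
#' @param seed optional integer seed.
#' @param height tree height after rescaling, Myr (bivalve-like depth).
#' @return an `ape::phylo` with tips `fam01, fam02, ...`.
#' @export
simulate_tree <- function(n_families, seed = NULL, height = 500) {
  if (n_families < 3) stop("need at least 3 families")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_families, birth = 0.1, death = 0.04)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * height / depth
  tree$tip.label <- sprintf("fam%02d", seq_len(n_families))
  tree
}

.stage_of <- function(age, scale) {
  # stage whose (base, top] interval contains the age; age 0 -> youngest
  idx <- findInterval(-age, -scale$base_age, left.open = TRUE)
  idx[age >= scale$base_age[1]] <- 1L
  idx[age <= 0] <- nrow(scale)
  pmin(pmax(idx, 1L), nrow(scale))
}

#' Simulate a fossil record with known extinction rates
#'
#' Per family, genera originate uniformly through the timescale and die at
#' the family's constant per-capita rate (exponential lifetimes); genera
#' outliving the timescale range to the youngest stage. First/last stages
#' are the stages containing the origination and extinction times.
#'
#' @param families character vector of family names.
#' @param q_true per-family true extinction rates (per Myr), recycled.
#' @param n_genera genera per family, recycled.
#' @param scale a [stage_scale()].
#' @param seed optional integer seed.
#' @return data.frame `genus, family, first_stage, last_stage` with the
#'   true rates in the `"q_true"` attribute.
#' @export
simulate_fossil_record <- function(families, q_true, n_genera = 40L,
                                   scale = cenozoic_stages(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q_true <- rep_len(q_true, length(families))
  n_genera <- rep_len(n_genera, length(families))
  base <- scale$base_age[1]
  rows <- lapply(seq_along(families), function(i) {
    n <- n_genera[i]
    t0 <- runif(n, 0, base)
    life <- if (q_true[i] > 0) rexp(n, q_true[i]) else rep(Inf, n)
    te <- pmax(t0 - life, 0)
    data.frame(genus = sprintf("%s_g%04d", families[i], seq_len(n)),
               family = families[i],
               first_stage = scale$name[.stage_of(t0, scale)],
               last_stage = scale$name[.stage_of(te, scale)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "q_true") <- setNames(q_true, families)
  out
}

#' Build an equal-area shelf grid with a latitudinal SST gradient
#'
#' Cells are squares of side `cell_size` km centred on the equator
#' (centroid `y = 0` at the grid's middle row); SST declines linearly with
#' |y| from `sst_eq` to `sst_pole` plus cell-level noise. Climate zones and
#' regions follow [assign_regions()], with an east/west coast label taken
#' from the sign of `x`.
#'
#' @param nx,ny grid dimensions in cells.
#' @param cell_size cell side, km.
#' @param sst_eq,sst_pole,sst_noise_sd SST field parameters (deg C).
#' @param seed optional integer seed.
#' @return a `shelf_grid` data.frame (`cell_id, x, y, sst_mean,
#'   climate_zone, region`) with a `cell_size` attribute.
#' @export
make_grid <- function(nx = 80, ny = 60, cell_size = 50,
                      sst_eq = 28, sst_pole = -2, sst_noise_sd = 0.5,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cx <- (seq_len(nx) - (nx + 1) / 2) * cell_size
  cy <- (seq_len(ny) - (ny + 1) / 2) * cell_size
  grid <- expand.grid(x = cx, y = cy)
  grid$cell_id <- sprintf("c%03d_r%03d",
                          match(grid$x, cx), match(grid$y, cy))
  ymax <- max(abs(cy))
  grid$sst_mean <- sst_eq + (sst_pole - sst_eq) * abs(grid$y) / ymax +
    rnorm(nrow(grid), 0, sst_noise_sd)
  grid <- grid[c("cell_id", "x", "y", "sst_mean")]
  attr(grid, "cell_size") <- cell_size
  class(grid) <- c("shelf_grid", "data.frame")
  coast <- ifelse(grid$x < 0, "west", "east")
  grid$climate_zone <- sub(" .*", "", assign_regions(grid))
  grid$region <- assign_regions(grid, coast = coast)
  grid
}

## Rectangular footprint of w x h cells placed uniformly at random; returns
## cell ids and the hull corner points (exactly on the block's outer
## boundary, so the hull reproduces the intended area and interior-strict
## intersection claims exactly the block's cells).
.place_footprint <- function(w, h, nx, ny, cell_size) {
  if (w > nx || h > ny) stop("footprint larger than grid")
  i0 <- sample.int(nx - w + 1L, 1L)
  j0 <- sample.int(ny - h + 1L, 1L)
  cols <- i0:(i0 + w - 1L); rows <- j0:(j0 + h - 1L)
  x0 <- (i0 - 1 - nx / 2) * cell_size; x1 <- x0 + w * cell_size
  y0 <- (j0 - 1 - ny / 2) * cell_size; y1 <- y0 + h * cell_size
  list(cells = as.vector(outer(cols, rows, function(i, j)
         sprintf("c%03d_r%03d", i, j))),
       points = cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
}

#' Simulate a fauna: traits, occupancy footprints and exploitation labels
#'
#' Species are assigned to the tree's families with lognormal family-size
#' weights; log10 range areas, log10 shell sizes and minimum bathymetries
#' are drawn from the configured distributions; each species receives a
#' contiguous rectangular block of grid cells sized to its range area
#' (a fraction `p_iso` of blocks follow isotherms), and its thermal range
#' is then *derived* from that footprint through [thermal_range()], so the
#' simulated trait correlations are realistic rather than assumed.
#' Exploitation labels are drawn from the logistic model
#' `logit P(exploited) = intercept + effects . z(traits) + u_family`.
#'
#' @param config a [sim_config()].
#' @param tree optional pre-built family tree (tips must be `fam01...`).
#' @return list with `records` (species data.frame in the canonical
#'   species-table schema plus `attached`), `occupancy` (named list of cell
#'   ids), `points` (named list of hull corner matrices), `grid`, `tree`,
#'   and `truth` (generating parameters: `effects`, `intercept`,
#'   `ranef_sd`, `u_family`, per-family `qhat`, and the latent z-scores).
#' @export
simulate_fauna <- function(config = sim_config(), tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_families; n <- config$n_species
  if (is.null(tree)) tree <- simulate_tree(nf)
  fams <- tree$tip.label

  # family sizes: lognormal weights
  w <- stats::rlnorm(nf, 0, 1)
  fam_of <- sample(fams, n, replace = TRUE, prob = w / sum(w))

  # true family-level clade volatility
  qhat_fam <- setNames(rgamma(nf, config$qhat_shape, config$qhat_rate), fams)

  # continuous traits (log10 scales where heavy-tailed)
  l_size <- rnorm(n, 1.5, 0.35)                       # log10 mm
  l_bathy <- pmax(rnorm(n, 0.5, 0.5), 0)              # log10 (m + 1)
  max_cells_x <- config$nx; max_cells_y <- config$ny
  max_l_gra <- log10(max_cells_x * max_cells_y * config$cell_size^2)
  l_gra <- pmin(rnorm(n, 4.2, 0.9), max_l_gra - 0.05) # log10 km2
  l_gra <- pmax(l_gra, log10(config$cell_size^2))     # at least one cell

  grid <- make_grid(config$nx, config$ny, config$cell_size,
                    config$sst_eq, config$sst_pole, config$sst_noise_sd)

  # footprints: w x h cell blocks matching the target areas
  occupancy <- vector("list", n)
  points <- vector("list", n)
  tr_c <- numeric(n)
  for (i in seq_len(n)) {
    n_cells <- max(1L, round(10^l_gra[i] / config$cell_size^2))
    iso <- runif(1) < config$p_iso
    if (iso) {
      h <- 1L
      w_c <- min(n_cells, max_cells_x)
    } else {
      h <- max(1L, round(sqrt(n_cells * runif(1, 0.5, 2))))
      h <- min(h, max_cells_y)
      w_c <- min(max(1L, round(n_cells / h)), max_cells_x)
    }
    fp <- .place_footprint(w_c, h, config$nx, config$ny, config$cell_size)
    occupancy[[i]] <- fp$cells
    points[[i]] <- fp$points
    tr_c[i] <- thermal_range(fp$cells, grid)
  }
  ids <- sprintf("sp%05d", seq_len(n))
  names(occupancy) <- names(points) <- ids

  gra_km2 <- vapply(points, geographic_range_area, numeric(1))
  attached <- runif(n) < 0.3

  z <- function(v) (v - mean(v)) / sd(v)
  zs <- cbind(size = z(l_size), min_bathymetry = z(l_bathy),
              geographic_range = z(log10(gra_km2)), thermal_range = z(tr_c))
  u <- setNames(rnorm(nf, 0, config$ranef_sd), fams)
  eta <- config$intercept +
    as.vector(zs[, names(config$effects)] %*% config$effects) +
    config$attachment_effect * attached + u[fam_of]
  exploited <- runif(n) < plogis(eta)

  records <- data.frame(
    species_id = ids, family = fam_of, exploited = exploited,
    in_fao = FALSE,
    size_mm = 10^l_size, min_bathy_m = 10^l_bathy - 1,
    gra_km2 = gra_km2, tr_c = tr_c,
    feeding = sample(c("suspension", "deposit", "carnivore", "other"), n,
                     replace = TRUE, prob = c(.7, .15, .1, .05)),
    attachment = ifelse(attached, "attached", "unattached"),
    mobility = sample(c("mobile", "immobile"), n, replace = TRUE,
                      prob = c(.6, .4)),
    position = sample(c("infaunal", "epifaunal"), n, replace = TRUE,
                      prob = c(.6, .4)),
    qhat = unname(qhat_fam[fam_of]), peril = NA_real_,
    stringsAsFactors = FALSE)

  list(records = records, occupancy = occupancy, points = points,
       grid = grid, tree = tree,
       truth = list(effects = config$effects,
                    attachment_effect = config$attachment_effect,
                    intercept = config$intercept, ranef_sd = config$ranef_sd,
                    u_family = u, qhat = qhat_fam, z = zs, seed = config$seed))
}

#' Synthetic species table shaped like the study's compiled trait dataset
#'
#' Generates a species trait table that reproduces, by construction, the
#' structural conditions of the compiled bivalve dataset: 6127 species in
#' 80 families; 801 exploited species of which 81 carry the FAO flag (720
#' literature additions); exploited species confined to 44 families, with a
#' scallop-like family (`fam01`, 62 exploited species, high clade
#' volatility) and an oyster-like family (`fam02`, 38 exploited); and 580
#' single-occurrence species at the 100 km2 range floor. Continuous traits
#' are drawn with exploited-species shifts in the established directions
#' (larger, shallower, wider-ranging, more eurythermal). The table is
#' synthetic: distribution-dependent statistics computed from it emulate,
#' but do not reproduce, the study's published values.
#'
#' @param seed integer seed.
#' @param n_species,n_families,n_exploited,n_fao,n_exploited_families,
#'   n_floor structural counts; defaults are the study's.
#' @return data.frame in the canonical species-table schema (see
#'   [species_table_columns()]); the per-family true `qhat` values are in
#'   the `"qhat_by_family"` attribute.
#' @export
simulate_s1_table <- function(seed = 1L, n_species = 6127L, n_families = 80L,
                              n_exploited = 801L, n_fao = 81L,
                              n_exploited_families = 44L, n_floor = 580L) {
  set.seed(seed)
  fams <- sprintf("fam%02d", seq_len(n_families))
  # species-rich families more likely exploited: lognormal sizes, two
  # designated analog families get fixed exploited counts
  w <- sort(stats::rlnorm(n_families, 0, 1.1), decreasing = TRUE)
  sizes <- as.integer(stats::rmultinom(1, n_species, w / sum(w)))
  floor_sizes <- c(70L, 45L, rep(1L, n_families - 2L))
  deficit <- pmax(floor_sizes - sizes, 0L)
  sizes <- pmax(sizes, floor_sizes)
  for (k in seq_len(sum(deficit))) {      # repay from the largest slack family
    donor <- which.max(sizes - floor_sizes)
    sizes[donor] <- sizes[donor] - 1L
  }
  stopifnot(sum(sizes) == n_species, all(sizes >= floor_sizes))
  fam_of <- rep(fams, sizes)

  # exploited allocation: fam01 (scallop analog) 62, fam02 (oyster analog)
  # 38, remainder across the other designated exploited families
  exploited <- logical(n_species)
  expl_fams <- fams[seq_len(n_exploited_families)]
  exploited[sample(which(fam_of == "fam01"), 62)] <- TRUE
  exploited[sample(which(fam_of == "fam02"), 38)] <- TRUE
  rest_fams <- setdiff(expl_fams, c("fam01", "fam02"))
  pool <- which(fam_of %in% rest_fams)
  n_rest <- n_exploited - 100L
  resample1 <- function(x) x[sample.int(length(x), 1L)]
  # at least one exploited species per exploited family
  first_of <- vapply(rest_fams, function(f) resample1(which(fam_of == f)), 0L)
  exploited[first_of] <- TRUE
  exploited[sample(setdiff(pool, first_of), n_rest - length(rest_fams))] <- TRUE

  in_fao <- logical(n_species)
  fao_fams <- expl_fams[seq_len(17)]
  fao_pool <- which(exploited & fam_of %in% fao_fams)
  in_fao[sample(fao_pool, n_fao)] <- TRUE

  # continuous traits: exploited-species shifts in SD units
  sh <- function(base_mu, sd, shift) base_mu + ifelse(exploited, shift * sd, 0)
  l_size <- rnorm(n_species, sh(1.45, 0.35, 0.8), 0.35)
  l_bathy <- pmax(rnorm(n_species, sh(0.55, 0.5, -0.5), 0.5), 0)
  l_gra <- rnorm(n_species, sh(4.6, 1.1, 0.5), 1.1)
  gra <- pmax(10^l_gra, 100)
  floor_idx <- order(gra)[seq_len(n_floor)]
  gra[floor_idx] <- 100
  tr <- rgamma(n_species, shape = 2.2,
               scale = ifelse(exploited, 4.5, 3.5))
  tr[sample(floor_idx, round(n_floor / 2))] <- 0   # single-cell species

  qhat_fam <- setNames(rgamma(n_families, 4, 25), fams)
  qhat_fam["fam01"] <- 0.32     # scallop analog: volatile clade

  records <- data.frame(
    species_id = sprintf("sp%05d", seq_len(n_species)),
    family = fam_of, exploited = exploited, in_fao = in_fao,
    size_mm = 10^l_size,
    min_bathy_m = ifelse(runif(n_species) < 0.35, 0, round(10^l_bathy - 1, 1)),
    gra_km2 = gra, tr_c = round(tr, 2),
    feeding = sample(c("suspension", "deposit", "chemosymbiotic",
                       "carnivore", "other"), n_species, replace = TRUE,
                     prob = c(.68, .15, .02, .1, .05)),
    attachment = sample(c("attached", "unattached"), n_species,
                        replace = TRUE, prob = c(.3, .7)),
    mobility = sample(c("mobile", "immobile"), n_species, replace = TRUE,
                      prob = c(.6, .4)),
    position = sample(c("infaunal", "epifaunal"), n_species, replace = TRUE,
                      prob = c(.65, .35)),
    qhat = unname(qhat_fam[fam_of]), peril = NA_real_,
    stringsAsFactors = FALSE)
  attr(records, "qhat_by_family") <- qhat_fam
  records
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits species CSV, occurrence CSV (hull corner points), grid GeoJSON,
#' tree newick, fossil-range CSV, stage-scale CSV and a ground-truth JSON,
#' all reproducible from the configuration seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture_set <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fauna <- simulate_fauna(config)
  fossil <- simulate_fossil_record(fauna$tree$tip.label,
                                   q_true = fauna$truth$qhat,
                                   n_genera = config$genera_per_family,
                                   seed = config$seed + 1L)
  pts <- do.call(rbind, lapply(names(fauna$points), function(id)
    data.frame(species_id = id, x_km = fauna$points[[id]][, 1],
               y_km = fauna$points[[id]][, 2])))
  paths <- c(species = file.path(dir, "species.csv"),
             occurrences = file.path(dir, "occurrences.csv"),
             grid = file.path(dir, "grid.geojson"),
             tree = file.path(dir, "tree.nwk"),
             fossil = file.path(dir, "fossil_ranges.csv"),
             stages = file.path(dir, "stage_scale.csv"),
             truth = file.path(dir, "truth.json"))
  write_species_table(fauna$records, paths["species"])
  write.csv(pts, paths["occurrences"], row.names = FALSE)
  write_shelf_grid(fauna$grid, paths["grid"])
  write_family_tree(fauna$tree, paths["tree"])
  write.csv(fossil, paths["fossil"], row.names = FALSE)
  write.csv(as.data.frame(cenozoic_stages())[c("name", "base_age", "top_age")],
            paths["stages"], row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, effects = as.list(fauna$truth$effects),
         attachment_effect = fauna$truth$attachment_effect,
         intercept = fauna$truth$intercept, ranef_sd = fauna$truth$ranef_sd,
         qhat = as.list(fauna$truth$qhat),
         package_version = as.character(packageVersion("perilscore"))),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
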