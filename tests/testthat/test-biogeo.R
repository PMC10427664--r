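toy_occupancy <- function() list(
  sp1 = c("c001_r001", "c002_r001"),
  sp2 = c("c001_r001"),
  sp3 = c("c003_r002", "c003_r003", "c002_r003"),
  sp4 = c("c002_r001"))

test_that("richness counts species per cell and matches a matrix oracle", {
  occ <- toy_occupancy()
  r <- richness_map(occ)
  expect_equal(r$n[r$cell_id == "c001_r001"], 2)
  expect_equal(sum(r$n), length(unlist(occ)))    # conservation
  sub <- richness_map(occ, species = c("sp1", "sp3"))
  expect_equal(sum(sub$n), 5)
  # random occupancy matrix vs column sums
  set.seed(77)
  cells <- sprintf("c%03d", 1:40)
  occ2 <- lapply(setNames(1:30, paste0("s", 1:30)), function(i)
    sample(cells, sample(1:10, 1)))
  m <- sapply(occ2, function(cs) as.integer(cells %in% cs))
  want <- rowSums(m)
  got <- richness_map(occ2)
  expect_equal(got$n[match(cells[want > 0], got$cell_id)],
               unname(want[want > 0]))
})

test_that("proportion map flags undefined cells and errors on misalignment", {
  den <- data.frame(cell_id = c("a", "b", "c"), n = c(20L, 0L, 4L))
  num <- data.frame(cell_id = c("a", "c"), n = c(5L, 4L))
  pm <- proportion_map(num, den)
  expect_equal(pm$prop[pm$cell_id == "a"], 0.25)
  expect_true(is.na(pm$prop[pm$cell_id == "b"]))
  expect_equal(pm$prop[pm$cell_id == "c"], 1)
  bad <- data.frame(cell_id = "zzz", n = 1L)
  expect_error(proportion_map(bad, den), "absent from denominator")
})

test_that("default region scheme is latitudinal; species take majority region", {
  grid <- make_grid(4, 80, cell_size = 50, seed = 1)  # spans high |lat|
  reg <- assign_regions(grid)
  lat <- asin(pmin(1, pmax(-1, grid$y / 6371))) * 180 / pi
  expect_true(all(reg[abs(lat) <= 23.44] == "tropical"))
  expect_true(all(reg[abs(lat) > 23.44 & abs(lat) <= 66.56] == "temperate"))
  # scheme override
  ov <- assign_regions(grid, scheme = data.frame(cell_id = grid$cell_id[1],
                                                 region = "special"))
  expect_equal(unname(ov[1]), "special")
  expect_error(assign_regions(grid, scheme = data.frame(cell_id = "zz",
                                                        region = "x")),
               "unknown cells")
})

test_that("species region follows majority rule with alphabetical ties", {
  cr <- c(c1 = "temperate", c2 = "temperate", c3 = "temperate",
          c4 = "tropical", c5 = "tropical", c6 = "polar")
  occ <- list(sp1 = c("c1", "c2", "c3", "c4"),   # 3 temperate 1 tropical
              sp2 = c("c4", "c5", "c1", "c2"),   # 2-2 tie
              sp3 = "c6")
  sr <- species_region(occ, cr)
  expect_equal(unname(sr["sp1"]), "temperate")
  expect_equal(unname(sr["sp2"]), "temperate")   # alphabetical first
  expect_equal(unname(sr["sp3"]), "polar")
})

test_that("vulnerability layer counts match hand enumeration on a toy fauna", {
  occ <- toy_occupancy()
  rec <- data.frame(species_id = paste0("sp", 1:4),
                    exploited = c(TRUE, FALSE, TRUE, TRUE),
                    peril = c(0.9, 0.2, 0.6, 0.1))
  # median = 0.4 -> vulnerable: sp1 (0.9), sp3 (0.6)
  v <- vulnerability_layer(rec, occ, quantile = 0.5, scope = "global")
  c11 <- v[v$cell_id == "c001_r001", ]
  expect_equal(c11$n_species, 2)
  expect_equal(c11$n_exploited, 1)
  expect_equal(c11$n_vulnerable, 1)
  expect_equal(c11$n_vulnerable_exploited, 1)
  expect_equal(c11$prop_exploited, 0.5)
  c23 <- v[v$cell_id == "c002_r003", ]
  expect_equal(c23$n_species, 1)
  expect_equal(c23$n_vulnerable_exploited, 1)
  # invariants across all cells
  expect_true(all(v$n_exploited <= v$n_species))
  expect_true(all(v$n_vulnerable_exploited <= pmin(v$n_vulnerable, v$n_exploited)))
  # quantile 0.999 on 4 species: at most one vulnerable
  v99 <- vulnerability_layer(rec, occ, quantile = 0.999, scope = "global")
  expect_lte(max(v99$n_vulnerable), 1)
})

test_that("all-vulnerable-exploited fauna yields proportions of 1", {
  occ <- toy_occupancy()[1:2]
  rec <- data.frame(species_id = c("sp1", "sp2"),
                    exploited = TRUE, peril = c(0.9, 0.95))
  v <- vulnerability_layer(rec, occ, quantile = 0.3, scope = "global")
  above <- vulnerable(rec$peril, 0.3)
  # with only two species, only the top one clears a strict threshold; all
  # species being exploited, every vulnerable species is exploited
  expect_true(all(v$prop_exploited_among_vulnerable[v$n_vulnerable > 0] == 1))
  expect_true(all(v$prop_exploited == 1))
  expect_equal(sum(above), 1)
})

test_that("raising the threshold never increases any cell's vulnerable count", {
  f <- simulate_fauna(sim_config(seed = 91, n_species = 200, n_families = 10))
  rec <- cbind(f$records[c("species_id", "exploited")],
               peril = peril_scores(peril(f$records)))
  qs <- c(0.3, 0.5, 0.7, 0.9)
  layers <- lapply(qs, function(q)
    vulnerability_layer(rec, f$occupancy, quantile = q, scope = "global"))
  for (k in seq_len(length(qs) - 1)) {
    m <- merge(layers[[k]], layers[[k + 1]], by = "cell_id")
    expect_true(all(m$n_vulnerable.y <= m$n_vulnerable.x))
  }
})

test_that("global-scope layer ignores the region scheme; regional differs", {
  f <- simulate_fauna(sim_config(seed = 92, n_species = 150, n_families = 8))
  rec <- cbind(f$records[c("species_id", "exploited")],
               peril = peril_scores(peril(f$records)))
  cr1 <- assign_regions(f$grid)
  cr2 <- setNames(sample(c("r1", "r2"), nrow(f$grid), TRUE), f$grid$cell_id)
  g1 <- vulnerability_layer(rec, f$occupancy, 0.5, "global", cell_regions = cr1)
  g2 <- vulnerability_layer(rec, f$occupancy, 0.5, "global", cell_regions = cr2)
  expect_equal(g1, g2)
  expect_equal(attr(g1, "threshold_scope"), "global")
  r1 <- suppressWarnings(
    vulnerability_layer(rec, f$occupancy, 0.5, "regional", cell_regions = cr1))
  expect_s3_class(r1, "vulnerability_layer")
})

test_that("vulnerability layer writes GeoJSON with a metadata sidecar", {
  f <- simulate_fauna(sim_config(seed = 93, n_species = 60, n_families = 6))
  rec <- cbind(f$records[c("species_id", "exploited")],
               peril = peril_scores(peril(f$records)))
  v <- vulnerability_layer(rec, f$occupancy, 0.8, "global")
  path <- withr::local_tempfile(fileext = ".geojson")
  write_vulnerability_layer(v, f$grid, path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$threshold_quantile, 0.8)
  expect_equal(meta$threshold_scope, "global")
  g <- jsonlite::read_json(path)
  expect_equal(length(g$features), nrow(f$grid))
})
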