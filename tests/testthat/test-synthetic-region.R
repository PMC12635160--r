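test_that("region generation is deterministic and seed-sensitive", {
  cfg <- small_config(seed = 11)
  r1 <- make_region(cfg)
  r2 <- make_region(cfg)
  expect_identical(r1$dem$values, r2$dem$values)
  expect_identical(r1$blockgroups, r2$blockgroups)
  expect_identical(r1$gauges, r2$gauges)
  expect_identical(r1$slr$samples, r2$slr$samples)

  r3 <- make_region(small_config(seed = 12))
  expect_false(identical(r1$dem$values, r3$dem$values))

  # sites + demographics stage is deterministic too
  s1 <- make_sites_and_demographics(r1)
  s2 <- make_sites_and_demographics(r2)
  expect_identical(s1$raw_sites, s2$raw_sites)
  expect_identical(s1$blockgroups, s2$blockgroups)
})

test_that("region geometry invariants hold", {
  r <- small_region()
  bg <- r$blockgroups
  # every block group lies in exactly one county (its centroid is covered
  # by exactly one county polygon, and the recorded id matches)
  for (i in seq_len(nrow(bg))) {
    ctr <- floodequity:::poly_centroid(bg$geometry[[i]])
    inside <- vapply(r$counties$geometry, function(g) {
      sp::point.in.polygon(ctr[1], ctr[2], g[, 1], g[, 2]) == 1
    }, logical(1))
    expect_equal(sum(inside), 1)
    expect_equal(r$counties$county_id[inside], bg$county_id[i])
  }
  # DEM ramps from ~0 at the coast to beyond 18 m inland
  colmeans <- colMeans(r$dem$values)
  expect_lt(colmeans[1], 2)
  expect_gt(max(colmeans), 18)
  expect_gt(stats::cor(seq_along(colmeans), colmeans), 0.9)
  # some counties contain land below 18 m and some do not
  min_by_county <- vapply(seq_len(nrow(r$counties)), function(i) {
    cells <- floodequity:::raster_cells_in_fp(
      r$dem, floodequity:::as_footprint(r$counties$geometry[[i]]))
    min(cells$values)
  }, numeric(1))
  expect_true(any(min_by_county < 18))
  expect_true(any(min_by_county >= 18))
  # population grid is nonnegative and totals the block-group populations
  expect_true(all(r$popgrid$values >= 0))
  expect_equal(sum(r$popgrid$values), sum(bg$population), tolerance = 1e-6)
  # demographic proportions are proportions, and race/ethnicity subgroups
  # are coherent
  for (cv in setdiff(floodequity:::COVARIATE_COLS, "cejst_disadvantaged")) {
    expect_true(all(bg[[cv]] >= 0 & bg[[cv]] <= 1), label = cv)
  }
  race_sum <- bg$p_hispanic + bg$p_black + bg$p_asian_pi + bg$p_native +
    bg$p_other_poc
  expect_true(all(race_sum <= 1 + 1e-9))
  expect_equal(race_sum, bg$p_poc, tolerance = 1e-9)
})

test_that("degenerate configs are rejected and n_counties = 1 is honored", {
  expect_error(region_config(extent_m = c(50, 50), cell_m = 100),
               "degenerate extent")
  expect_error(region_config(slr_samples = 50))
  expect_error(region_config(n_counties = 10, n_blockgroups = 5))
  expect_error(region_config(duplicate_rate = 1))

  r1 <- make_region(small_config(n_counties = 1, n_blockgroups = 12))
  expect_equal(unique(r1$blockgroups$county_id), "C01")
})

test_that("SLR projections order by year and scenario and are reproducible", {
  gauges <- tibble::tibble(gauge_id = c("A", "B"))
  slr <- make_slr_projections(gauges, seed = 5, n_samples = 300)
  slr2 <- make_slr_projections(gauges, seed = 5, n_samples = 300)
  expect_identical(slr$samples, slr2$samples)
  m <- function(g, sc, yr) mean(slr$samples[[which(slr$gauge_id == g &
    slr$scenario == sc & slr$year == yr)]])
  for (g in c("A", "B")) {
    expect_gt(m(g, "RCP85", 2100), m(g, "RCP85", 2050))
    expect_gt(m(g, "RCP85", 2100), m(g, "RCP45", 2100))
  }
  expect_error(make_slr_projections(gauges[0, ]), "empty gauge")
  expect_error(make_slr_projections(gauges, scenarios = "RCP99"))
})

test_that("duplicate injection follows the configured rate", {
  r0 <- small_region(seed = 21, duplicate_rate = 0)
  key <- paste(r0$raw_sites$x, r0$raw_sites$y, r0$raw_sites$truth_category)
  clean <- !is.na(r0$raw_sites$truth_category)
  expect_false(any(duplicated(key[clean])))

  r1 <- small_region(seed = 21, duplicate_rate = 0.2)
  key1 <- paste(r1$raw_sites$x, r1$raw_sites$y, r1$raw_sites$truth_category)
  expect_gt(sum(duplicated(key1[!is.na(r1$raw_sites$truth_category)])), 0)
})

test_that("null association leaves the covariate uncorrelated with exposure", {
  # pooled over seeds: ~5000 block groups under assoc_log_odds = 0
  rho <- vapply(1:3, function(sd) {
    cfg <- region_config(seed = 100 + sd, extent_m = c(24000, 18000),
                         cell_m = 150, n_counties = 8, n_blockgroups = 1700,
                         n_sites_per_category = c(oil_gas_well = 120),
                         n_gauges = 3, slr_samples = 150,
                         assoc_log_odds = 0, with_popgrid = FALSE)
    r <- make_sites_and_demographics(make_region(cfg))
    suppressWarnings(stats::cor(r$blockgroups$p_poverty,
                                as.numeric(r$truth$bg_exposed$exposed_true),
                                method = "spearman"))
  }, numeric(1))
  expect_lt(abs(mean(rho)), 0.05)
})

test_that("positive association shifts the covariate among exposed block groups", {
  r <- small_region(seed = 31, assoc_log_odds = log(1.4))
  e <- r$truth$bg_exposed$exposed_true
  expect_gt(sum(e), 2)
  expect_gt(mean(r$blockgroups$p_poverty[e]),
            mean(r$blockgroups$p_poverty[!e]))
})

test_that("fixture bundles round-trip through GeoJSON / ASCII grid / CSV", {
  r <- small_region(seed = 41)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(r, dir)
  expect_true(all(c("dem", "counties", "blockgroups", "parcels", "coastline",
                    "raw_sites", "gauges", "slr", "truth") %in%
                    names(manifest$layers)))
  expect_match(manifest$crs, "meters")
  expect_true(all(file.exists(file.path(dir, unlist(manifest$layers)))))

  r2 <- read_fixture_bundle(dir)
  expect_equal(r2$dem$values, r$dem$values, tolerance = 1e-9)
  expect_equal(r2$popgrid$values, r$popgrid$values, tolerance = 1e-9)
  expect_equal(r2$counties$geometry, r$counties$geometry, tolerance = 1e-9)
  expect_equal(r2$blockgroups$geometry, r$blockgroups$geometry, tolerance = 1e-9)
  expect_equal(as.data.frame(r2$blockgroups[, c("bg_id", "county_id", "p_poverty")]),
               as.data.frame(r$blockgroups[, c("bg_id", "county_id", "p_poverty")]),
               tolerance = 1e-12)
  expect_equal(r2$raw_sites$address, r$raw_sites$address)
  s1 <- dplyr::arrange(r$slr, gauge_id, scenario, year)
  s2 <- dplyr::arrange(r2$slr, gauge_id, scenario, year)
  expect_equal(s2$samples, s1$samples, tolerance = 1e-12)
  expect_equal(s2$median_m, s1$median_m, tolerance = 1e-12)
  # FUDS polygon geometries survive
  has_poly <- !vapply(r$raw_sites$geometry, is.null, logical(1))
  expect_equal(r2$raw_sites$geometry[has_poly], r$raw_sites$geometry[has_poly],
               tolerance = 1e-9)
})
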