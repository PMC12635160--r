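# Synthetic coastal study regions.
#
# The generator builds a self-contained planar coastal region with the
# statistical structure the downstream analysis assumes: a DEM ramping from
# the MHHW datum at the coast to >18 m inland with spatially correlated
# noise, counties and block groups tiling the land, a 30 m population grid,
# tide gauges with Poisson-GPD return curves, sample-based probabilistic SLR
# projections, hazardous-site registries with injected duplicates and junk
# records, tax parcels, and block-group demographics with a known
# exposure-marginalization association. Everything is a pure function of
# (config, seed).

SITE_CATEGORIES <- c("power_plant", "animal_operation", "sewage_treatment",
                     "hazardous_waste_tsd", "tri_industrial", "solid_waste",
                     "cleanup_radioactive", "refinery", "fossil_port_terminal",
                     "oil_gas_well", "fuds")

# Evaluate code under a fixed seed without disturbing the caller's RNG.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic coastal region
#'
#' @param seed integer RNG seed; the region is a pure function of the config
#' @param extent_m width x height of the planar region in meters (land spans
#'   x in \[0, width\]; the coastline is the line x = 0)
#' @param cell_m DEM / population-grid resolution (m)
#' @param n_counties number of counties
#' @param n_blockgroups number of block groups (>= n_counties)
#' @param n_sites_per_category named integer vector over site categories
#' @param duplicate_rate fraction of clean site records re-injected as
#'   near-duplicates (same coordinates and category, perturbed address)
#' @param n_gauges tide gauges along the coast
#' @param slr_samples SLR samples per gauge x scenario x year (>= 100)
#' @param assoc_log_odds true standardized log-odds linking the
#'   marginalization covariate to 1-km exposure
#' @param assoc_covariate which block-group covariate carries the association
#' @param with_popgrid generate the 30 m population raster; `FALSE` exercises
#'   the block-group-only fallback used where gridded estimates are missing
#' @param inland_counties include counties with no land below 18 m (they are
#'   screened out of the study area upstream of the equity analysis)
#' @param max_elev_m inland end of the elevation ramp (m above MHHW)
#' @param plain_frac fraction of the region width occupied by the low
#'   coastal plain before the ramp begins
#' @param plain_elev_m base elevation of the coastal plain (m above MHHW)
#' @param noise_sd_m sd of the spatially correlated DEM noise (m)
#' @param noise_scale_m correlation scale of the DEM noise field (m)
#' @param site_scale_m e-folding distance of site density decay inland (m)
#' @param n_parcels number of tax parcels (default scales with site count)
#' @return a `region_config` list
#' @export
region_config <- function(seed = 1L,
                          extent_m = c(20000, 12000),
                          cell_m = 30,
                          n_counties = 4L,
                          n_blockgroups = 60L,
                          n_sites_per_category = c(tri_industrial = 30,
                                                   sewage_treatment = 10,
                                                   power_plant = 6,
                                                   oil_gas_well = 40,
                                                   fuds = 8),
                          duplicate_rate = 0.05,
                          n_gauges = 3L,
                          slr_samples = 500L,
                          assoc_log_odds = log(1.4),
                          assoc_covariate = "p_poverty",
                          with_popgrid = TRUE,
                          inland_counties = TRUE,
                          max_elev_m = 40,
                          plain_frac = 0.12,
                          plain_elev_m = 0.6,
                          noise_sd_m = 1.0,
                          noise_scale_m = 1000,
                          site_scale_m = NULL,
                          n_parcels = NULL) {
  stopifnot(length(extent_m) == 2, all(extent_m > 0), cell_m > 0,
            duplicate_rate >= 0, duplicate_rate < 1,
            slr_samples >= 100, n_blockgroups >= n_counties,
            n_counties >= 1, n_gauges >= 1, max_elev_m > 18,
            plain_frac >= 0, plain_frac < 0.5, plain_elev_m >= 0,
            noise_scale_m > 0)
  if (floor(extent_m[1] / cell_m) * floor(extent_m[2] / cell_m) < 4) {
    stop("degenerate extent: region must span at least 4 DEM cells")
  }
  bad <- setdiff(names(n_sites_per_category), SITE_CATEGORIES)
  if (length(bad) > 0) stop("unknown site categories: ", paste(bad, collapse = ", "))
  if (is.null(site_scale_m)) site_scale_m <- max(1500, 0.10 * extent_m[1])
  if (is.null(n_parcels)) {
    n_nonwell <- sum(n_sites_per_category[setdiff(names(n_sites_per_category),
                                                  c("oil_gas_well", "fuds"))])
    n_parcels <- max(10L, as.integer(ceiling(1.5 * n_nonwell)))
  }
  structure(list(seed = as.integer(seed), extent_m = extent_m, cell_m = cell_m,
                 n_counties = as.integer(n_counties),
                 n_blockgroups = as.integer(n_blockgroups),
                 n_sites_per_category = n_sites_per_category,
                 duplicate_rate = duplicate_rate,
                 n_gauges = as.integer(n_gauges),
                 slr_samples = as.integer(slr_samples),
                 assoc_log_odds = assoc_log_odds,
                 assoc_covariate = assoc_covariate,
                 with_popgrid = isTRUE(with_popgrid),
                 inland_counties = isTRUE(inland_counties),
                 max_elev_m = max_elev_m, plain_frac = plain_frac,
                 plain_elev_m = plain_elev_m, noise_sd_m = noise_sd_m,
                 noise_scale_m = noise_scale_m,
                 site_scale_m = site_scale_m,
                 n_parcels = as.integer(n_parcels)),
            class = "region_config")
}

# Split k into a nr x nc grid as square as possible for a w x h rectangle
# (nr must divide k so the tiling is exact).
tile_counts <- function(k, w, h) {
  divs <- seq_len(k)[k %% seq_len(k) == 0]
  score <- abs(log((h / divs) / (w / (k / divs))))
  nr <- divs[which.min(score)]
  c(nr = nr, nc = k / nr)
}

tile_rect <- function(xmin, ymin, xmax, ymax, k) {
  tc <- tile_counts(k, xmax - xmin, ymax - ymin)
  xs <- seq(xmin, xmax, length.out = tc["nc"] + 1)
  ys <- seq(ymin, ymax, length.out = tc["nr"] + 1)
  out <- vector("list", k)
  i <- 1L
  for (c in seq_len(tc["nc"])) for (r in seq_len(tc["nr"])) {
    out[[i]] <- rect_polygon(xs[c], ys[r], xs[c + 1], ys[r + 1])
    i <- i + 1L
  }
  out
}

# Spatially correlated noise field: coarse Gaussian control grid, bilinear
# interpolation to cell centers.
correlated_noise <- function(nrows, ncols, sd, nctrl = c(7L, 9L)) {
  nctrl <- pmax(nctrl, 2L)
  ctrl <- matrix(stats::rnorm(prod(nctrl), sd = sd), nctrl[1], nctrl[2])
  ry <- seq(1, nctrl[1], length.out = nrows)
  rx <- seq(1, nctrl[2], length.out = ncols)
  y0 <- pmin(floor(ry), nctrl[1] - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), nctrl[2] - 1L); fx <- rx - x0
  a <- ctrl[cbind(rep(y0, ncols), rep(x0, each = nrows))]
  b <- ctrl[cbind(rep(y0, ncols), rep(x0 + 1L, each = nrows))]
  cc <- ctrl[cbind(rep(y0 + 1L, ncols), rep(x0, each = nrows))]
  d <- ctrl[cbind(rep(y0 + 1L, ncols), rep(x0 + 1L, each = nrows))]
  wfx <- rep(fx, each = nrows); wfy <- rep(fy, ncols)
  v <- a * (1 - wfx) * (1 - wfy) + b * wfx * (1 - wfy) +
    cc * (1 - wfx) * wfy + d * wfx * wfy
  matrix(v, nrows, ncols)
}

#' Generate a synthetic coastal region
#'
#' Builds the DEM, coastline, counties, block groups, population grid, tide
#' gauges with return curves, and probabilistic SLR projections. Sites,
#' parcels and demographics are added by [make_sites_and_demographics()].
#'
#' @param config a [region_config()]
#' @return a `synthetic_region` list
#' @export
make_region <- function(config) {
  stopifnot(inherits(config, "region_config"))
  local_seed(config$seed, {
    cell <- config$cell_m
    ncols <- max(2L, floor(config$extent_m[1] / cell))
    nrows <- max(2L, floor(config$extent_m[2] / cell))
    # grid-align the region so every feature lies on the DEM
    W <- ncols * cell; H <- nrows * cell

    # DEM: a low coastal plain (where flood-risk variation is driven by the
    # correlated noise field) rising through a linear ramp to >18 m inland;
    # noise is damped to ~0 at the coastline
    cx <- (seq_len(ncols) - 0.5) * cell
    x_plain <- config$plain_frac * W
    ramp_x <- config$max_elev_m * pmax(cx - x_plain, 0) / max(W - x_plain, cell)
    ramp <- matrix(rep(config$plain_elev_m + ramp_x, each = nrows),
                   nrows, ncols)
    nctrl <- c(max(2L, ceiling(H / config$noise_scale_m)) + 1L,
               max(2L, ceiling(W / config$noise_scale_m)) + 1L)
    noise <- correlated_noise(nrows, ncols, config$noise_sd_m, nctrl)
    damp <- matrix(rep(pmin(1, cx / (0.05 * W)), each = nrows), nrows, ncols)
    dem <- grid_raster(pmax(ramp + noise * damp, 0), xmin = 0, ymin = 0,
                       cell = cell)

    # counties: coastal strips plus (optionally) fully-inland strips beyond
    # the elevation where the ramp clears 18 m with margin
    n_inland <- if (config$inland_counties && config$n_counties >= 3) {
      max(1L, config$n_counties %/% 5L)
    } else 0L
    n_coastal <- config$n_counties - n_inland
    x_split <- if (n_inland > 0) {
      min(x_plain + (W - x_plain) *
            (18 + 4 * config$noise_sd_m - config$plain_elev_m) /
            config$max_elev_m, 0.9 * W)
    } else W
    cty_geom <- c(
      tile_rect(0, 0, x_split, H, n_coastal),
      if (n_inland > 0) tile_rect(x_split, 0, W, H, n_inland)
    )
    counties <- tibble::tibble(
      county_id = sprintf("C%02d", seq_along(cty_geom)),
      geometry = cty_geom,
      is_coastal = c(rep(TRUE, n_coastal), rep(FALSE, n_inland))
    )

    # block groups: allocate to counties by area (largest remainder, min 1)
    areas <- vapply(counties$geometry, poly_area, numeric(1))
    quota <- config$n_blockgroups * areas / sum(areas)
    k <- pmax(1L, floor(quota))
    rem <- config$n_blockgroups - sum(k)
    if (rem > 0) {
      ord <- order(quota - floor(quota), decreasing = TRUE)
      k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
    } else if (rem < 0) {
      ord <- order(k, decreasing = TRUE)
      i <- 1L
      while (rem < 0) {
        if (k[ord[i]] > 1L) { k[ord[i]] <- k[ord[i]] - 1L; rem <- rem + 1L }
        i <- if (i == length(k)) 1L else i + 1L
      }
    }
    bg_geom <- list(); bg_cty <- character(0)
    for (i in seq_len(nrow(counties))) {
      g <- counties$geometry[[i]]
      tiles <- tile_rect(min(g[, 1]), min(g[, 2]), max(g[, 1]), max(g[, 2]), k[i])
      bg_geom <- c(bg_geom, tiles)
      bg_cty <- c(bg_cty, rep(counties$county_id[i], k[i]))
    }
    pop <- round(stats::runif(length(bg_geom), 600, 3000))
    bg_area <- vapply(bg_geom, poly_area, numeric(1))
    blockgroups <- tibble::tibble(
      bg_id = sprintf("BG%04d", seq_along(bg_geom)),
      county_id = bg_cty,
      geometry = bg_geom,
      area_m2 = bg_area,
      population = pop,
      density_km2 = pop / bg_area * 1e6
    )

    popgrid <- if (config$with_popgrid) {
      make_popgrid(blockgroups, dem)
    } else NULL

    # tide gauges along the coast with Poisson-GPD return-curve parameters
    gauges <- tibble::tibble(
      gauge_id = sprintf("G%02d", seq_len(config$n_gauges)),
      x = 0,
      y = (seq_len(config$n_gauges) - 0.5) * H / config$n_gauges,
      lambda_rate = stats::runif(config$n_gauges, 2, 5),
      threshold_mu = stats::runif(config$n_gauges, 0.7, 1.2),
      scale_sigma = stats::runif(config$n_gauges, 0.08, 0.2),
      shape_xi = stats::runif(config$n_gauges, -0.05, 0.15),
      cap_rate = 182.6
    )

    region <- structure(list(
      config = config,
      land = rect_polygon(0, 0, W, H),
      coastline = cbind(c(0, 0), c(0, H)),
      dem = dem,
      counties = counties,
      blockgroups = blockgroups,
      popgrid = popgrid,
      gauges = gauges,
      slr = NULL,
      parcels = NULL,
      raw_sites = NULL,
      truth = list(seed = config$seed,
                   assoc_log_odds = config$assoc_log_odds,
                   assoc_covariate = config$assoc_covariate)
    ), class = "synthetic_region")
    region$slr <- make_slr_projections(gauges, seed = config$seed + 1000L,
                                       n_samples = config$slr_samples)
    region$truth$slr_medians <- region$slr[, c("gauge_id", "scenario", "year",
                                               "median_m")]
    region
  })
}

# Scatter block-group populations over their cells with density decaying
# from the centroid; a low-weight fraction of cells is zeroed so block
# groups have genuinely unpopulated portions.
make_popgrid <- function(blockgroups, dem) {
  d <- dim(dem$values)
  vals <- matrix(0, d[1], d[2])
  cxs <- dem$xmin + (seq_len(d[2]) - 0.5) * dem$cell
  cys <- dem$ymin + (seq_len(d[1]) - 0.5) * dem$cell
  for (i in seq_len(nrow(blockgroups))) {
    g <- blockgroups$geometry[[i]]
    cols <- which(cxs > min(g[, 1]) & cxs < max(g[, 1]))
    rows <- which(cys > min(g[, 2]) & cys < max(g[, 2]))
    if (length(cols) == 0 || length(rows) == 0) {
      # block group smaller than a cell: dump population in nearest cell
      ctr <- poly_centroid(g)
      rr <- pmin(d[1], pmax(1L, floor((ctr[2] - dem$ymin) / dem$cell) + 1L))
      cc <- pmin(d[2], pmax(1L, floor((ctr[1] - dem$xmin) / dem$cell) + 1L))
      vals[rr, cc] <- vals[rr, cc] + blockgroups$population[i]
      next
    }
    ctr <- poly_centroid(g)
    dx <- outer(cys[rows] - ctr[2], cxs[cols] - ctr[1],
                function(a, b) sqrt(a^2 + b^2))
    tau <- 0.35 * sqrt(poly_area(g))
    w <- exp(-dx / tau) * stats::runif(length(dx), 0.2, 1)
    w[w < stats::quantile(w, 0.35)] <- 0
    if (sum(w) == 0) w[which.max(exp(-dx / tau))] <- 1
    vals[rows, cols] <- vals[rows, cols] + blockgroups$population[i] * w / sum(w)
  }
  grid_raster(vals, xmin = dem$xmin, ymin = dem$ymin, cell = dem$cell)
}

#' Probabilistic SLR projections per gauge, scenario and year
#'
#' Samples local sea-level rise from shifted lognormal distributions whose
#' location grows with year and is higher under RCP8.5 than RCP4.5 in 2100.
#' Within a gauge and year the two scenarios share base draws so the RCP8.5
#' sample distribution stochastically dominates RCP4.5 pointwise.
#'
#' @param gauges gauge tibble (needs `gauge_id`)
#' @param scenarios subset of `c("RCP45", "RCP85")`
#' @param years subset of `c(2050, 2100)`
#' @param seed RNG seed
#' @param n_samples samples per distribution (>= 100)
#' @return tibble: gauge_id, scenario, year, samples (list-column), median_m
#' @export
make_slr_projections <- function(gauges, scenarios = c("RCP45", "RCP85"),
                                 years = c(2050, 2100), seed = 1L,
                                 n_samples = 500L) {
  if (is.null(gauges) || nrow(gauges) == 0) stop("empty gauge list")
  stopifnot(all(scenarios %in% c("RCP45", "RCP85")),
            all(years %in% c(2050, 2100)), n_samples >= 100)
  loc <- list(`2050` = c(RCP45 = 0.15, RCP85 = 0.18),
              `2100` = c(RCP45 = 0.35, RCP85 = 0.55))
  spread <- list(`2050` = c(meanlog = log(0.10), sdlog = 0.45),
                 `2100` = c(meanlog = log(0.22), sdlog = 0.60))
  mult <- c(RCP45 = 0.9, RCP85 = 1.0)
  local_seed(seed, {
    rows <- list()
    for (gi in seq_len(nrow(gauges))) {
      jitter <- stats::runif(1, -0.02, 0.02)  # gauge-specific VLM-style offset
      for (yr in years) {
        sp <- spread[[as.character(yr)]]
        base <- stats::rlnorm(n_samples, sp["meanlog"], sp["sdlog"])
        for (sc in scenarios) {
          s <- loc[[as.character(yr)]][sc] + jitter + mult[sc] * base
          rows[[length(rows) + 1L]] <- tibble::tibble(
            gauge_id = gauges$gauge_id[gi], scenario = sc,
            year = as.integer(yr), samples = list(unname(s)),
            median_m = stats::median(s))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat(sprintf(
    "<synthetic_region> %.1f x %.1f km, %d counties, %d block groups, %d gauges%s\n",
    x$config$extent_m[1] / 1000, x$config$extent_m[2] / 1000,
    nrow(x$counties), nrow(x$blockgroups), nrow(x$gauges),
    if (is.null(x$raw_sites)) "" else sprintf(", %d raw site records",
                                              nrow(x$raw_sites))))
  invisible(x)
}
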