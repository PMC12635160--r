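# Synthetic hazardous-site registries, parcels, and block-group
# demographics with a known exposure-marginalization association.

COVARIATE_COLS <- c("p_renters", "p_poverty", "p_poc", "p_hispanic", "p_black",
                    "p_asian_pi", "p_native", "p_other_poc", "p_ling_iso",
                    "p_no_vehicle", "p_single_parent", "p_under18", "p_over65",
                    "p_nonvoter", "cejst_disadvantaged")

# category -> (program code, NAICS, keyword); the default rulebook mirrors
# this table
CATEGORY_HINTS <- tibble::tribble(
  ~category,             ~program, ~naics,  ~keyword,
  "refinery",            "REF",    "32411", "refinery",
  "fossil_port_terminal","PRT",    "42471", "petroleum terminal",
  "power_plant",         "PWR",    "2211",  "power plant",
  "sewage_treatment",    "POTW",   "22132", "wastewater treatment",
  "hazardous_waste_tsd", "TSDF",   "5622",  "hazardous waste",
  "solid_waste",         "SWL",    "5621",  "landfill",
  "cleanup_radioactive", "CLN",    NA,      "radioactive cleanup",
  "animal_operation",    "AFO",    "1121",  "feedlot",
  "oil_gas_well",        "WELL",   "2111",  "oil well",
  "fuds",                "FUDS",   NA,      "defense site",
  "tri_industrial",      "TRI",    "3251",  "chemical manufacturing"
)

STREET_NAMES <- c("Harbor", "Bayview", "Dockside", "Estuary", "Marsh", "Gull",
                  "Cannery", "Pier", "Salt", "Dune", "Heron", "Anchor",
                  "Terrace", "Levee", "Mill", "Quarry", "Cypress", "Pelican",
                  "Lagoon", "Driftwood")
STREET_TYPES <- c("St", "Ave", "Rd", "Blvd", "Ln", "Way")

make_address <- function(n) {
  paste(sample(10:9999, n, replace = TRUE),
        sample(STREET_NAMES, n, replace = TRUE),
        sample(STREET_TYPES, n, replace = TRUE))
}

# Perturbation operators emulating real-world address entry noise:
# abbreviation expansion, case changes, and single-character typos.
perturb_address <- function(addr) {
  vapply(addr, function(a) {
    op <- sample(3L, 1L)
    if (op == 1L) {
      a <- sub("\\bSt$", "Street", a)
      a <- sub("\\bAve$", "Avenue", a)
      a <- sub("\\bRd$", "Road", a)
      a <- sub("\\bLn$", "Lane", a)
    } else if (op == 2L) {
      a <- toupper(a)
    } else {
      i <- sample(nchar(a), 1L)
      substr(a, i, i) <- sample(c(letters, " "), 1L)
    }
    a
  }, character(1), USE.NAMES = FALSE)
}

# Random convex polygon (hull of points in a disc of radius ~r).
random_convex_poly <- function(center, r, npts = 12L) {
  th <- stats::runif(npts, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(npts, 0.25, 1))
  convex_hull_poly(cbind(center[1] + rr * cos(th), center[2] + rr * sin(th)))
}

shift_poly <- function(p, dx, dy = 0) cbind(p[, 1] + dx, p[, 2] + dy)

overlap_ratio_polys <- function(p, q) {
  inter <- poly_clip(p, q)
  a <- if (is.null(inter)) 0 else poly_area(inter)
  a / min(poly_area(p), poly_area(q))
}

# Shift a scaled copy of p along +x until the overlap ratio hits `target`.
overlap_partner <- function(p, target, scale = 0.85) {
  ctr <- poly_centroid(p)
  q0 <- cbind(ctr[1] + scale * (p[, 1] - ctr[1]),
              ctr[2] + scale * (p[, 2] - ctr[2]))
  lo <- 0; hi <- diff(range(p[, 1])) + diff(range(q0[, 1]))
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (overlap_ratio_polys(p, shift_poly(q0, mid)) > target) lo <- mid
    else hi <- mid
  }
  shift_poly(q0, (lo + hi) / 2)
}

#' Add hazardous-site registries, parcels and demographics to a region
#'
#' Sites are placed with density decaying inland; near-duplicate records,
#' no-hint records, imprecise/closed records and offshore wells are injected
#' to exercise the cleaning rules. Block-group marginalization covariates are
#' drawn so that the configured covariate follows a logistic model for 1-km
#' exposure with county intercepts and standardized slope
#' `config$assoc_log_odds`; the generative parameters are recorded in
#' `region$truth`.
#'
#' @param region output of [make_region()]
#' @param config the region's [region_config()] (defaults to the one stored
#'   on the region)
#' @return the updated `synthetic_region`
#' @export
make_sites_and_demographics <- function(region, config = region$config) {
  stopifnot(inherits(region, "synthetic_region"), !is.null(region$slr))
  local_seed(config$seed + 2000L, {
    W <- max(region$land[, 1]); H <- max(region$land[, 2])
    nsc <- config$n_sites_per_category
    nsc <- nsc[nsc > 0]

    rows <- list()
    fuds_geoms <- list()
    for (cat in names(nsc)) {
      n <- nsc[[cat]]
      x <- stats::rexp(4 * n, rate = 1 / config$site_scale_m)
      x <- x[x < 0.95 * W][seq_len(n)]
      x[is.na(x)] <- stats::runif(sum(is.na(x)), 0, 0.5 * W)
      x <- pmax(x, config$cell_m)
      y <- stats::runif(n, 0, H)
      hint <- CATEGORY_HINTS[CATEGORY_HINTS$category == cat, ]
      program <- rep(hint$program, n)
      naics <- rep(hint$naics, n)
      keyword <- ifelse(stats::runif(n) < 0.3, hint$keyword, NA_character_)
      # some records carry only a generic discharge permit plus the NAICS
      # code, exercising rule priority
      if (!is.na(hint$naics)) {
        generic <- stats::runif(n) < 0.15
        program[generic] <- "NPDES"
      }
      active <- stats::runif(n) > 0.10  # retained even when inactive
      end_date <- rep(NA_integer_, n)
      accuracy <- stats::runif(n, 1, 30)
      rows[[cat]] <- tibble::tibble(
        source = if (cat == "oil_gas_well") "WELLS" else
          if (cat == "fuds") "FUDS" else "FRS",
        address = make_address(n), x = x, y = y,
        program = program, naics = naics, keyword = keyword,
        active = active, end_date = end_date, accuracy_m = accuracy,
        geometry = vector("list", n), truth_category = cat)
    }
    sites <- dplyr::bind_rows(rows)

    # FUDS polygons: engineered overlap pairs (split-range and merge-range
    # ratios) among otherwise non-overlapping polygons
    if ("fuds" %in% names(nsc)) {
      idx <- which(sites$truth_category == "fuds")
      n_poly <- max(0L, length(idx) - ceiling(length(idx) / 3))
      if (n_poly > 0) {
        pid <- idx[seq_len(n_poly)]
        for (k in seq_along(pid)) {
          i <- pid[k]
          sites$geometry[[i]] <- random_convex_poly(
            c(sites$x[i], sites$y[i]), stats::runif(1, 100, 260))
        }
        if (n_poly >= 2) {
          sites$geometry[[pid[2]]] <- overlap_partner(sites$geometry[[pid[1]]], 0.30)
          ctr <- poly_centroid(sites$geometry[[pid[2]]])
          sites$x[pid[2]] <- ctr[1]; sites$y[pid[2]] <- ctr[2]
        }
        if (n_poly >= 4) {
          sites$geometry[[pid[4]]] <- overlap_partner(sites$geometry[[pid[3]]], 0.60)
          ctr <- poly_centroid(sites$geometry[[pid[4]]])
          sites$x[pid[4]] <- ctr[1]; sites$y[pid[4]] <- ctr[2]
        }
      }
    }

    n_clean <- nrow(sites)

    # junk: imprecise locations and pre-2020 closures (filtered out later)
    n_junk <- max(2L, round(0.06 * n_clean))
    junk_src <- sites[sample(n_clean, n_junk, replace = TRUE), ]
    junk_src$address <- make_address(n_junk)
    junk_src$x <- stats::runif(n_junk, 0, 0.5 * W)
    junk_src$y <- stats::runif(n_junk, 0, H)
    junk_src$geometry <- vector("list", n_junk)
    imprecise <- stats::runif(n_junk) < 0.5
    junk_src$accuracy_m[imprecise] <- stats::runif(sum(imprecise), 55, 500)
    junk_src$end_date[!imprecise] <- sample(2000:2020, sum(!imprecise),
                                            replace = TRUE)
    junk_src$truth_category <- NA_character_

    # records matching no categorization rule
    n_nohint <- max(1L, round(0.03 * n_clean))
    nohint <- tibble::tibble(
      source = "FRS", address = make_address(n_nohint),
      x = stats::runif(n_nohint, 0, 0.5 * W), y = stats::runif(n_nohint, 0, H),
      program = NA_character_, naics = NA_character_, keyword = NA_character_,
      active = TRUE, end_date = NA_integer_,
      accuracy_m = stats::runif(n_nohint, 1, 30),
      geometry = vector("list", n_nohint), truth_category = NA_character_)

    # offshore wells, seaward of every block group
    offshore <- NULL
    if ("oil_gas_well" %in% names(nsc)) {
      n_off <- max(1L, round(0.05 * nsc[["oil_gas_well"]]))
      offshore <- tibble::tibble(
        source = "WELLS", address = make_address(n_off),
        x = stats::runif(n_off, -2000, -100), y = stats::runif(n_off, 0, H),
        program = "WELL", naics = "2111", keyword = NA_character_,
        active = TRUE, end_date = NA_integer_,
        accuracy_m = stats::runif(n_off, 1, 30),
        geometry = vector("list", n_off), truth_category = "oil_gas_well")
    }

    # near-duplicates: identical coordinates and category, perturbed address
    dups <- NULL
    n_dup <- round(config$duplicate_rate * n_clean)
    if (n_dup > 0) {
      dup_idx <- sample(n_clean, n_dup)
      dups <- sites[dup_idx, ]
      dups$address <- perturb_address(dups$address)
      dups$geometry <- vector("list", n_dup)
    }

    raw <- dplyr::bind_rows(sites, dups, junk_src, nohint, offshore)
    raw$record_id <- sprintf("R%05d", seq_len(nrow(raw)))
    raw <- raw[, c("record_id", "source", "address", "x", "y", "program",
                   "naics", "keyword", "active", "end_date", "accuracy_m",
                   "geometry", "truth_category")]

    # tax parcels: most centered on non-well, non-FUDS site coordinates so
    # the point-in-parcel join fires, the rest scattered
    pcl_cat <- !(sites$truth_category %in% c("oil_gas_well", "fuds"))
    anchors <- which(pcl_cat)
    n_anchor <- min(length(anchors), round(0.7 * config$n_parcels))
    n_rand <- config$n_parcels - n_anchor
    picked <- if (n_anchor > 0) sample(anchors, n_anchor) else integer(0)
    acx <- c(sites$x[picked], stats::runif(n_rand, 0, 0.5 * W))
    acy <- c(sites$y[picked], stats::runif(n_rand, 0, H))
    pw <- exp(stats::rnorm(config$n_parcels, log(90), 0.4))
    ph <- exp(stats::rnorm(config$n_parcels, log(90), 0.4))
    jx <- stats::runif(config$n_parcels, -20, 20)
    jy <- stats::runif(config$n_parcels, -20, 20)
    parcels <- tibble::tibble(
      parcel_id = sprintf("P%04d", seq_len(config$n_parcels)),
      geometry = purrr::pmap(list(acx + jx, acy + jy, pw, ph), function(cx, cy, w, h) {
        rect_polygon(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
      }))

    region$raw_sites <- raw
    region$parcels <- parcels

    # ---- generative flood-risk truth (clean records, point elevations) ----
    curves <- flood_curves_tbl(region$gauges)
    gd <- as.matrix(region$gauges[, c("x", "y")])
    clean_idx <- which(!is.na(raw$truth_category) & raw$x > 0 &
                         !duplicated(paste(raw$x, raw$y, raw$truth_category)))
    pts <- as.matrix(raw[clean_idx, c("x", "y")])
    nearest_g <- apply(pts, 1, function(p) {
      which.min((gd[, 1] - p[1])^2 + (gd[, 2] - p[2])^2)
    })
    z <- raster_value_at(region$dem, pts)
    n0 <- function(zz, cv) mean(expected_exceedances(zz, cv))
    risk <- purrr::map_dfr(seq_along(clean_idx), function(i) {
      g <- region$gauges$gauge_id[nearest_g[i]]
      s85 <- region$slr$samples[[which(region$slr$gauge_id == g &
                                         region$slr$scenario == "RCP85" &
                                         region$slr$year == 2100)]]
      ne <- mean(expected_exceedances(z[i] - s85, curves[[g]]))
      ne_deg <- expected_exceedances(z[i] - stats::median(s85), curves[[g]])
      tibble::tibble(record_id = raw$record_id[clean_idx[i]],
                     gauge_id = g, z_point = z[i],
                     expected_floods = ne, p_annual = -expm1(-ne),
                     at_risk = -expm1(-ne) >= 0.01,
                     p_degenerate = -expm1(-ne_deg),
                     at_risk_degenerate = -expm1(-ne_deg) >= 0.01)
    })
    region$truth$site_risk <- risk

    # ---- generative exposure truth at 1 km --------------------------------
    risk_pts <- pts[risk$at_risk, , drop = FALSE]
    exposed <- bg_points_within(region$blockgroups, risk_pts, 1000,
                                region$popgrid)
    region$truth$bg_exposed <- tibble::tibble(
      bg_id = region$blockgroups$bg_id, exposed_true = exposed)

    # ---- demographics -----------------------------------------------------
    bg <- region$blockgroups
    n_bg <- nrow(bg)
    race <- rdirichlet_rows(n_bg, c(1.8, 1.2, 0.8, 0.15, 0.5, 4.5))
    age <- rdirichlet_rows(n_bg, c(2.0, 2.5, 6.0))
    demo <- tibble::tibble(
      p_hispanic = race[, 1], p_black = race[, 2], p_asian_pi = race[, 3],
      p_native = race[, 4], p_other_poc = race[, 5],
      p_poc = 1 - race[, 6],
      p_under18 = age[, 1], p_over65 = age[, 2],
      p_renters = stats::rbeta(n_bg, 2.2, 3.3),
      p_poverty = stats::rbeta(n_bg, 2.5, 6.0),
      p_ling_iso = stats::rbeta(n_bg, 1.2, 12),
      p_no_vehicle = stats::rbeta(n_bg, 1.5, 10),
      p_single_parent = stats::rbeta(n_bg, 2.5, 10),
      p_nonvoter = stats::rbeta(n_bg, 7.5, 18),
      cejst_disadvantaged = as.integer(stats::runif(n_bg) < 0.3))

    # marginalization covariate tied to exposure through a logistic model
    lin_map <- c(mu = 0.35, s = 0.10)
    zlat <- draw_latent_given_exposure(exposed, bg$county_id,
                                       config$assoc_log_odds)
    demo[[config$assoc_covariate]] <-
      pmin(0.999, pmax(0.001, lin_map["mu"] + lin_map["s"] * zlat$z))
    region$truth$assoc <- list(
      log_odds = config$assoc_log_odds,
      covariate = config$assoc_covariate,
      linear_map = lin_map,
      county_intercepts = zlat$intercepts)

    region$blockgroups <- dplyr::bind_cols(
      bg[, setdiff(names(bg), names(demo))], demo)
    region
  })
}

rdirichlet_rows <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# For each block group: is any of the given points within `radius` of the
# populated part (popgrid cells with population > 0, or the polygon itself
# in fallback mode)?
bg_points_within <- function(blockgroups, pts, radius, popgrid = NULL) {
  n_bg <- nrow(blockgroups)
  if (is.null(pts) || nrow(pts) == 0) return(rep(FALSE, n_bg))
  out <- logical(n_bg)
  for (i in seq_len(n_bg)) {
    g <- blockgroups$geometry[[i]]
    bx <- range(g[, 1]); by <- range(g[, 2])
    cand <- pts[, 1] >= bx[1] - radius & pts[, 1] <= bx[2] + radius &
      pts[, 2] >= by[1] - radius & pts[, 2] <= by[2] + radius
    if (!any(cand)) next
    p <- pts[cand, , drop = FALSE]
    if (is.null(popgrid)) {
      dx <- pmax(bx[1] - p[, 1], p[, 1] - bx[2], 0)
      dy <- pmax(by[1] - p[, 2], p[, 2] - by[2], 0)
      out[i] <- any(sqrt(dx^2 + dy^2) <= radius)
    } else {
      cells <- raster_cells_in_fp(popgrid, as_footprint(g))
      keep <- cells$values > 0
      if (!any(keep)) next
      cc <- cells$centers[keep, , drop = FALSE]
      for (j in seq_len(nrow(p))) {
        if (min(sqrt((cc[, 1] - p[j, 1])^2 + (cc[, 2] - p[j, 2])^2)) <= radius) {
          out[i] <- TRUE; break
        }
      }
    }
  }
  out
}

# Draw a latent covariate whose conditional law given exposure reproduces
# P(exposed | z, county) = plogis(a_county + b * z), with spatial (tract-
# scale) autocorrelation. County intercepts are calibrated to the realized
# county exposure rates; z is then drawn through a Gaussian copula whose
# uniform is mapped through the Bayes-implied conditional quantile function,
# so each observation keeps the exact conditional marginal (hence the exact
# standardized logistic slope b) while neighboring block groups are
# positively correlated -- the spatial autocorrelation that motivates
# county-clustered standard errors in the analysis model.
draw_latent_given_exposure <- function(exposed, county, b, tract = NULL,
                                       rho = 0.35) {
  n <- length(exposed)
  if (is.null(tract)) {
    # consecutive block groups within a county tile adjacent cells
    tract <- paste(county, ave(seq_len(n), county,
                               FUN = function(i) (seq_along(i) - 1L) %/% 8L))
  }
  tau <- stats::rnorm(length(unique(tract)))
  names(tau) <- unique(tract)
  w <- sqrt(rho) * tau[tract] + sqrt(1 - rho) * stats::rnorm(n)
  u <- stats::pnorm(unname(w))

  intercepts <- stats::setNames(rep(NA_real_, length(unique(county))),
                                sort(unique(county)))
  z <- stats::qnorm(u)
  if (b == 0) return(list(z = z, intercepts = intercepts))

  grid <- seq(-6, 6, by = 0.005)
  phi <- stats::dnorm(grid)
  for (cty in names(intercepts)) {
    idx <- which(county == cty)
    r <- mean(exposed[idx])
    if (r <= 0 || r >= 1) next  # no exposure variation: covariate uninformative
    marg <- function(a) {
      stats::integrate(function(t) stats::plogis(a + b * t) * stats::dnorm(t),
                       -Inf, Inf)$value - r
    }
    a <- stats::uniroot(marg, c(-20, 20))$root
    intercepts[cty] <- a
    sig <- stats::plogis(a + b * grid)
    for (e in c(TRUE, FALSE)) {
      tgt <- idx[exposed[idx] == e]
      if (length(tgt) == 0) next
      f <- phi * (if (e) sig else 1 - sig)
      cdf <- cumsum(f); cdf <- cdf / cdf[length(cdf)]
      keep <- c(TRUE, diff(cdf) > 0)
      z[tgt] <- stats::approx(cdf[keep], grid[keep], xout = u[tgt],
                              rule = 2)$y
    }
  }
  list(z = z, intercepts = intercepts)
}
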