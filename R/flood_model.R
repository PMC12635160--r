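# Annual flood exceedance probabilities under probabilistic sea-level rise.
#
# A tide gauge's flood climatology is a Poisson-generalized-Pareto (GPD)
# return curve: above a threshold height mu the expected annual number of
# exceedances of height z is
#
#   N0(z) = lambda * (1 + xi * (z - mu) / sigma)^(-1/xi)        (xi != 0)
#   N0(z) = lambda * exp(-(z - mu) / sigma)                     (xi -> 0)
#
# with a finite upper endpoint mu - sigma/xi when xi < 0. Below the
# threshold, where the GPD fit does not apply, the curve is extended
# log-linearly from (mu, lambda) down to (0, cap_rate) and held constant at
# cap_rate for z <= 0, reflecting that heights at or below the MHHW datum
# are exceeded on the order of every high tide.
#
# Local sea-level rise s shifts the effective height of a site of elevation
# z to z - s. Integrating over a sample-based SLR distribution by the law of
# total probability gives the expected annual flood count
#   N_e(z) = E_s[ N0(z - s) ]
# and, with Poisson arrivals, the annual probability of at least one flood
#   p = 1 - exp(-N_e).

XI_EPS <- 1e-8

#' Construct a tide-gauge flood return curve
#'
#' @param gauge_id identifier
#' @param lambda_rate mean annual number of threshold exceedances (events/yr)
#' @param threshold_mu GPD threshold height (m above MHHW)
#' @param scale_sigma GPD scale (m)
#' @param shape_xi GPD shape (dimensionless)
#' @param cap_rate annual flood count applied at and below the MHHW datum
#'   (events/yr); default 182.6 is the order of one exceedance per day's
#'   higher high tide
#' @return a `flood_curve` object (also a plain list, one row per gauge when
#'   vectorized via [flood_curves_tbl()])
#' @export
flood_curve <- function(gauge_id, lambda_rate, threshold_mu, scale_sigma,
                        shape_xi, cap_rate = 182.6) {
  stopifnot(lambda_rate > 0, scale_sigma > 0, cap_rate >= lambda_rate,
            is.finite(threshold_mu), is.finite(shape_xi))
  structure(list(gauge_id = gauge_id, lambda_rate = lambda_rate,
                 threshold_mu = threshold_mu, scale_sigma = scale_sigma,
                 shape_xi = shape_xi, cap_rate = cap_rate),
            class = "flood_curve")
}

#' @export
print.flood_curve <- function(x, ...) {
  cat(sprintf(
    "<flood_curve %s> lambda=%.3g/yr, mu=%.3g m, sigma=%.3g m, xi=%.3g, cap=%.4g/yr\n",
    x$gauge_id, x$lambda_rate, x$threshold_mu, x$scale_sigma, x$shape_xi,
    x$cap_rate))
  invisible(x)
}

#' Expected annual exceedances of a water height
#'
#' Evaluates the Poisson-GPD return curve: expected number of floods per
#' year exceeding height `z` (m above MHHW). Vectorized over `z`.
#'
#' @param z height(s) in meters above MHHW
#' @param curve a [flood_curve()]
#' @return expected annual exceedance count(s), events/yr
#' @export
expected_exceedances <- function(z, curve) {
  if (any(!is.finite(z))) stop("non-finite height passed to expected_exceedances()")
  lam <- curve$lambda_rate; mu <- curve$threshold_mu
  sig <- curve$scale_sigma; xi <- curve$shape_xi; cap <- curve$cap_rate

  out <- numeric(length(z))
  above <- z >= mu
  if (any(above)) {
    za <- z[above] - mu
    if (abs(xi) < XI_EPS) {
      out[above] <- lam * exp(-za / sig)
    } else {
      arg <- 1 + xi * za / sig
      n0 <- ifelse(arg > 0, lam * arg^(-1 / xi), 0)  # beyond upper endpoint
      out[above] <- n0
    }
  }
  below <- !above & z > 0
  if (any(below)) {
    # log-linear between (0, cap) and (mu, lambda)
    out[below] <- exp(log(cap) + (z[below] / mu) * (log(lam) - log(cap)))
  }
  out[z <= 0] <- cap
  out
}

#' Annual flood probability for a site elevation under an SLR distribution
#'
#' Integrates the return curve across the full sample-based distribution of
#' local sea-level rise by the law of total probability (sample-mean Monte
#' Carlo over the complete array, no subsampling), then converts the expected
#' annual count to the probability of at least one flood via the Poisson
#' relation p = 1 - exp(-N).
#'
#' @param elevation_q25 site elevation (m above MHHW), conventionally the
#'   25th percentile over the site footprint
#' @param slr_samples numeric vector of local sea-level change samples (m)
#' @param curve a [flood_curve()]
#' @param gauge_id optional; if supplied it must match `curve$gauge_id`
#' @return named list with `expected_floods` (events/yr) and `p_annual`
#' @export
annual_flood_probability <- function(elevation_q25, slr_samples, curve,
                                     gauge_id = NULL) {
  if (!is.null(gauge_id) && !identical(gauge_id, curve$gauge_id)) {
    stop(sprintf("gauge mismatch: SLR samples are for '%s', curve is '%s'",
                 gauge_id, curve$gauge_id))
  }
  stopifnot(is.finite(elevation_q25), all(is.finite(slr_samples)))
  n_e <- mean(expected_exceedances(elevation_q25 - slr_samples, curve))
  list(expected_floods = n_e, p_annual = -expm1(-n_e))
}

#' Classify a site as at risk of SLR-related flooding
#'
#' A site is at risk when its annual flood probability reaches the
#' 1-in-100-year criterion.
#'
#' @param p_annual annual flood probability (or vector)
#' @param threshold classification boundary, default 0.01; the comparison is
#'   inclusive (`p >= threshold`)
#' @param on under `"p"` (default) the criterion applies to the probability
#'   `1 - exp(-N)`; under `"rate"` it applies to the expected count `N`
#'   itself (pass `expected_floods` as the first argument)
#' @return logical vector
#' @export
classify_at_risk <- function(p_annual, threshold = 0.01, on = c("p", "rate")) {
  on <- match.arg(on)
  stopifnot(all(p_annual >= 0), on != "p" || all(p_annual <= 1))
  p_annual >= threshold
}

#' Per-site flood-risk table for one scenario and year
#'
#' @param sites tibble of cleaned sites with columns `site_id`, `category`,
#'   `elevation_q25`, `gauge_id`
#' @param slr tibble of SLR projections: `gauge_id`, `scenario`, `year`,
#'   `samples` (list-column of numeric vectors)
#' @param curves named list of [flood_curve()] objects keyed by gauge id
#' @param scenario,year scenario ("RCP45"/"RCP85") and year (2050/2100)
#' @param risk_threshold at-risk boundary on the annual probability
#' @return tibble: site_id, category, scenario, year, expected_floods,
#'   p_annual, at_risk
#' @export
site_risk_table <- function(sites, slr, curves, scenario, year,
                            risk_threshold = 0.01) {
  if (nrow(sites) == 0) {
    return(tibble::tibble(site_id = character(), category = character(),
                          scenario = character(), year = integer(),
                          expected_floods = numeric(), p_annual = numeric(),
                          at_risk = logical()))
  }
  slr_sub <- slr[slr$scenario == scenario & slr$year == year, , drop = FALSE]
  need <- unique(sites$gauge_id)
  missing_g <- setdiff(need, intersect(slr_sub$gauge_id, names(curves)))
  if (length(missing_g) > 0) {
    stop(sprintf("no return curve and/or SLR distribution (%s, %s) for gauge(s): %s",
                 scenario, year, paste(missing_g, collapse = ", ")))
  }
  sample_by_gauge <- stats::setNames(slr_sub$samples, slr_sub$gauge_id)
  res <- purrr::map2(sites$elevation_q25, sites$gauge_id, function(z, g) {
    annual_flood_probability(z, sample_by_gauge[[g]], curves[[g]])
  })
  n_e <- vapply(res, `[[`, numeric(1), "expected_floods")
  p <- vapply(res, `[[`, numeric(1), "p_annual")
  tibble::tibble(
    site_id = sites$site_id,
    category = sites$category,
    scenario = scenario,
    year = as.integer(year),
    expected_floods = n_e,
    p_annual = p,
    at_risk = classify_at_risk(p, threshold = risk_threshold)
  )
}

#' Curve list from a gauges table
#'
#' @param gauges tibble with gauge_id, lambda_rate, threshold_mu,
#'   scale_sigma, shape_xi, cap_rate
#' @return named list of [flood_curve()] keyed by gauge id
#' @export
flood_curves_tbl <- function(gauges) {
  out <- purrr::pmap(
    gauges[, c("gauge_id", "lambda_rate", "threshold_mu", "scale_sigma",
               "shape_xi", "cap_rate")],
    flood_curve)
  stats::setNames(out, gauges$gauge_id)
}

#' Return-curve plot
#'
#' Expected annual exceedances against height above MHHW on a log rate axis.
#' @param curve a [flood_curve()]
#' @param zmax upper height (m); default just past the 1-in-500-yr level
#' @return a ggplot object
#' @export
plot_return_curve <- function(curve, zmax = NULL) {
  if (is.null(zmax)) {
    xi <- curve$shape_xi
    zmax <- if (xi < -XI_EPS) curve$threshold_mu - curve$scale_sigma / xi
            else curve$threshold_mu +
              curve$scale_sigma * ((curve$lambda_rate / 0.002)^max(xi, 0.0) + 5)
  }
  z <- seq(0, zmax, length.out = 400)
  df <- tibble::tibble(z = z, n = expected_exceedances(z, curve))
  ggplot2::ggplot(df[df$n > 0, ], ggplot2::aes(x = z, y = n)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "height above MHHW (m)",
                  y = "expected annual exceedances (events/yr)",
                  title = sprintf("Flood return curve, gauge %s", curve$gauge_id))
}
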