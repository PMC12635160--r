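# Exposure-disparity statistics: descriptive group comparisons,
# standardized county-fixed-effects regressions with county-clustered
# robust errors, and concentration curves / indices with bootstrap CIs.

#' Compare covariate distributions between exposed and unexposed block groups
#'
#' Medians and quartiles by exposure group plus a tie-corrected two-sided
#' Mann-Whitney U p-value per covariate. No multiplicity adjustment is
#' applied.
#'
#' @param data block-group tibble with an exposure flag and covariates
#' @param covariates character vector of covariate column names
#' @param exposed_col name of the logical exposure column
#' @return tibble: covariate, group medians and quartiles, n by group, p
#' @export
compare_exposed_unexposed <- function(data, covariates, exposed_col = "exposed") {
  e <- data[[exposed_col]]
  stopifnot(is.logical(e), any(e), any(!e))
  skipped <- character(0)
  rows <- purrr::map(covariates, function(cv) {
    x <- data[[cv]]
    if (is.null(x) || all(is.na(x))) {
      skipped <<- c(skipped, cv)
      return(NULL)
    }
    x1 <- x[e & !is.na(x)]; x0 <- x[!e & !is.na(x)]
    p <- if (length(unique(c(x0, x1))) == 1L) 1 else
      suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE,
                                          correct = TRUE)$p.value)
    tibble::tibble(
      covariate = cv,
      median_exposed = stats::median(x1), q25_exposed = unname(stats::quantile(x1, 0.25)),
      q75_exposed = unname(stats::quantile(x1, 0.75)),
      median_unexposed = stats::median(x0), q25_unexposed = unname(stats::quantile(x0, 0.25)),
      q75_unexposed = unname(stats::quantile(x0, 0.75)),
      n_exposed = length(x1), n_unexposed = length(x0),
      p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Standardize covariates over the analysis universe
#'
#' Scales continuous covariates to zero mean and unit standard deviation
#' using the mean and SD over all rows supplied (the full coastal
#' universe, not only exposed block groups). Binary covariates (values in
#' \{0, 1\}) are left unscaled.
#'
#' @param data block-group tibble (the universe)
#' @param covariates column names to scale
#' @return `data` with scaled columns; scaling constants in
#'   `attr(, "scaling")`
#' @export
standardize <- function(data, covariates) {
  scaling <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (all(x %in% c(0, 1, NA))) {
      scaling[[cv]] <- c(mean = NA_real_, sd = NA_real_)  # binary, untouched
      next
    }
    m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("covariate '%s' has zero variance in the universe", cv))
    }
    data[[cv]] <- (x - m) / s
    scaling[[cv]] <- c(mean = m, sd = s)
  }
  attr(data, "scaling") <- scaling
  data
}

#' Fit a standardized exposure model with county fixed effects
#'
#' One marginalization covariate per model, with block-group population
#' density and county fixed effects as additional independent variables.
#' Standard errors are county-clustered one-way sandwich estimates with the
#' finite-cluster correction G/(G-1) * (N-1)/(N-k); 95% CIs use the normal
#' quantile on the estimation scale (log scale for OR / IRR).
#'
#' @param data model frame (typically standardized via [standardize()]);
#'   count and linear models are conventionally fit on exposed block groups
#'   only
#' @param outcome outcome column: logical/0-1 (logistic), count (negbin),
#'   or continuous (linear)
#' @param covariate the single marginalization covariate column
#' @param family "logistic", "negbin" or "linear"
#' @param density_col population-density column
#' @param county_col county-id column (fixed effects and clustering unit)
#' @return an `exposure_fit` object; see [tidy.exposure_fit()]
#' @export
fit_exposure_model <- function(data, outcome, covariate,
                               family = c("logistic", "negbin", "linear"),
                               density_col = "density_km2",
                               county_col = "county_id") {
  family <- match.arg(family)
  cols <- c(outcome, covariate, density_col, county_col)
  df <- data[stats::complete.cases(data[, cols]), cols]
  names(df) <- c(".y", ".x", ".dens", ".county")
  if (is.logical(df$.y)) df$.y <- as.integer(df$.y)

  n_dropped_counties <- 0L
  if (family == "logistic") {
    varies <- tapply(df$.y, df$.county, function(v) length(unique(v)) > 1)
    keep <- names(varies)[varies]
    n_dropped_counties <- sum(!varies)
    df <- df[df$.county %in% keep, , drop = FALSE]
  }
  df$.county <- factor(df$.county)
  if (nlevels(df$.county) < 2) {
    stop("fewer than 2 counties with usable data: county clustering undefined")
  }

  fml <- .y ~ .x + .dens + .county
  fit <- switch(family,
    logistic = stats::glm(fml, data = df, family = stats::binomial()),
    negbin = MASS::glm.nb(fml, data = df),
    linear = stats::lm(fml, data = df))
  cf <- stats::coef(fit)[".x"]
  if (family != "linear" && (!isTRUE(fit$converged) || abs(cf) > 15)) {
    stop("model did not converge (possible complete separation)")
  }

  vc <- sandwich::vcovCL(fit, cluster = df$.county, type = "HC1",
                         cadjust = TRUE)
  se <- sqrt(vc[".x", ".x"])
  measure <- switch(family, logistic = "OR", negbin = "IRR",
                    linear = "mean_difference")
  if (family == "linear") {
    point <- unname(cf); lo <- point - 1.96 * se; hi <- point + 1.96 * se
  } else {
    point <- exp(unname(cf)); lo <- point * exp(-1.96 * se)
    hi <- point * exp(1.96 * se)
  }
  structure(list(fit = fit, family = family, measure = measure,
                 covariate = covariate, outcome = outcome,
                 coef = unname(cf), se_cluster = unname(se),
                 estimate = point, ci_low = lo, ci_high = hi,
                 n = nrow(df), n_counties = nlevels(df$.county),
                 n_dropped_counties = n_dropped_counties,
                 vcov_cluster = vc),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("<exposure_fit> %s model, %s ~ %s\n", x$family, x$outcome,
              x$covariate))
  cat(sprintf("  %s = %.3f [%.3f, %.3f], cluster SE(log/raw) = %.3f\n",
              x$measure, x$estimate, x$ci_low, x$ci_high, x$se_cluster))
  cat(sprintf("  n = %d block groups, %d counties (%d dropped)\n",
              x$n, x$n_counties, x$n_dropped_counties))
  invisible(x)
}

#' Tidy an exposure-model fit
#'
#' One-row effect estimate for the marginalization covariate on the
#' reporting scale (OR, IRR or mean difference) with county-clustered 95% CI.
#' @param x an `exposure_fit`
#' @param ... unused
#' @exportS3Method generics::tidy
tidy.exposure_fit <- function(x, ...) {
  tibble::tibble(covariate = x$covariate, model = x$family,
                 measure = x$measure, estimate = x$estimate,
                 std_error = x$se_cluster,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n = x$n, n_counties = x$n_counties)
}

#' Model-level summary of an exposure-model fit
#' @param x an `exposure_fit`
#' @param ... unused
#' @exportS3Method generics::glance
glance.exposure_fit <- function(x, ...) {
  tibble::tibble(model = x$family, n = x$n, n_counties = x$n_counties,
                 n_dropped_counties = x$n_dropped_counties,
                 aic = tryCatch(stats::AIC(x$fit), error = function(e) NA_real_))
}

## ---- concentration curves and indices ------------------------------------

#' Concentration curve of a burden over ranked block groups
#'
#' Block groups are ordered by descending marginalization rank value; the
#' curve gives the cumulative share of total burden (y) against the
#' cumulative share of block groups (x), piecewise linear from (0,0) to
#' (1,1). Ties in the ranking variable are broken by stable input order, or
#' pooled into a single step with `ties = "pool"`.
#'
#' @param rank_values marginalization measure used for ordering
#' @param burdens nonnegative block-group burdens (site counts or EAE)
#' @param ties "order" (stable) or "pool"
#' @return tibble with columns x, y (class `concentration_curve`)
#' @export
concentration_curve <- function(rank_values, burdens, ties = c("order", "pool")) {
  ties <- match.arg(ties)
  stopifnot(length(rank_values) == length(burdens), all(burdens >= 0))
  if (sum(burdens) == 0) stop("all burdens are zero: curve undefined")
  ord <- order(-rank_values)
  b <- burdens[ord]
  n <- length(b)
  if (ties == "pool") {
    g <- match(rank_values[ord], unique(rank_values[ord]))
    x <- cumsum(as.numeric(table(g)[as.character(unique(g))])) / n
    y <- cumsum(as.numeric(tapply(b, g, sum)[as.character(unique(g))])) / sum(b)
  } else {
    x <- seq_len(n) / n
    y <- cumsum(b) / sum(b)
  }
  out <- tibble::tibble(x = c(0, x), y = c(0, y))
  class(out) <- c("concentration_curve", class(out))
  out
}

#' Concentration index from a curve
#'
#' C = 1 - 2A where A is the trapezoid area under the piecewise-linear
#' concentration curve. Under descending-rank ordering a curve above the
#' diagonal (burden concentrated among marginalized block groups) gives
#' C < 0; C lies in \[-1, 1\].
#'
#' @param curve a [concentration_curve()] (or any tibble with x, y)
#' @return the concentration index
#' @export
concentration_index <- function(curve) {
  x <- curve$x; y <- curve$y
  stopifnot(!is.unsorted(x), !is.unsorted(y))
  a <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  1 - 2 * a
}

#' Bootstrap confidence interval for the concentration index
#'
#' Nonparametric bootstrap over block groups with a percentile 95% interval;
#' deterministic for a fixed seed. The disparity is called significant when
#' the interval excludes zero.
#'
#' @param rank_values,burdens as in [concentration_curve()]
#' @param n_boot bootstrap replicates (>= 100)
#' @param seed RNG seed
#' @param ties tie handling passed to [concentration_curve()]
#' @return list: index, ci_low, ci_high, significant, n_boot
#' @export
concentration_ci <- function(rank_values, burdens, n_boot = 1000, seed = 1L,
                             ties = "order") {
  if (n_boot < 100) stop("n_boot must be at least 100")
  n <- length(burdens)
  if (n < 10) stop("need at least 10 block groups for a bootstrap CI")
  c_hat <- concentration_index(concentration_curve(rank_values, burdens,
                                                   ties = ties))
  boots <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(burdens[idx]) == 0) return(NA_real_)
      concentration_index(concentration_curve(rank_values[idx], burdens[idx],
                                              ties = ties))
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(index = c_hat, ci_low = qs[1], ci_high = qs[2],
       significant = qs[1] > 0 || qs[2] < 0, n_boot = n_boot)
}

#' Plot a concentration curve against the line of equality
#' @param curve a [concentration_curve()]
#' @param label optional curve label for the title
#' @return a ggplot object
#' @export
plot_concentration_curve <- function(curve, label = NULL) {
  ggplot2::ggplot(curve, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "cumulative share of block groups (descending marginalization)",
      y = "cumulative share of burden",
      title = if (is.null(label)) "Concentration curve" else
        sprintf("Concentration curve: %s", label))
}

#' @rdname plot_concentration_curve
#' @param object a `concentration_curve`
#' @param ... passed on
#' @exportS3Method ggplot2::autoplot
autoplot.concentration_curve <- function(object, ...) {
  plot_concentration_curve(object, ...)
}
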