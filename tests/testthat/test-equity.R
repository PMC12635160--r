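test_that("exposed/unexposed comparison gives medians, quartiles and MW p-values", {
  set.seed(1)
  n <- 400
  d <- tibble::tibble(
    exposed = rep(c(TRUE, FALSE), each = n / 2),
    same = rnorm(n),
    shifted = c(rnorm(n / 2, 2), rnorm(n / 2, 0)),
    constant = 0.5,
    empty = NA_real_)
  out <- compare_exposed_unexposed(d, c("same", "shifted", "constant", "empty"))
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "skipped"), "empty")
  expect_gt(out$p_value[out$covariate == "same"], 0.05)
  expect_lt(out$p_value[out$covariate == "shifted"], 1e-3)
  expect_equal(out$p_value[out$covariate == "constant"], 1)
  srt <- sort(d$shifted[d$exposed])
  expect_equal(out$median_exposed[out$covariate == "shifted"], median(srt))
  expect_equal(out$q25_exposed[out$covariate == "shifted"],
               unname(quantile(srt, 0.25)))

  # strictly separated groups at n = 20 per group
  d2 <- tibble::tibble(exposed = rep(c(TRUE, FALSE), each = 20),
                       v = c(21:40, 1:20) / 40)
  expect_lt(compare_exposed_unexposed(d2, "v")$p_value, 0.001)
})

test_that("standardization is exact and leaves binary indicators alone", {
  d <- tibble::tibble(a = c(0.2, 0.3, 0.4), flag = c(0, 1, 0), cst = 2)
  z <- standardize(d, c("a", "flag"))
  expect_equal(mean(z$a), 0, tolerance = 1e-12)
  expect_equal(sd(z$a), 1, tolerance = 1e-12)
  expect_equal(z$flag, c(0, 1, 0))
  # hand value: x = 0.4, mean 0.3, sd 0.1 -> 1
  expect_equal(z$a[3], 1, tolerance = 1e-9)
  expect_error(standardize(d, "cst"), "zero variance")
})

test_that("logistic FE fit reproduces the closed-form cross-product ratio", {
  # two counties with identical 2x2 tables: exposed|x=1 = 30/40,
  # exposed|x=0 = 20/60 -> OR = (30*40)/(10*20)
  mk <- function(cty) tibble::tibble(
    exposed = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 20, 40)),
    x = rep(c(1, 1, 0, 0), c(30, 10, 20, 40)),
    density_km2 = 1, county_id = cty)
  d <- dplyr::bind_rows(mk("A"), mk("B"))
  fit <- fit_exposure_model(d, "exposed", "x", "logistic")
  expect_equal(fit$estimate, (30 * 40) / (10 * 20), tolerance = 1e-6)
  expect_equal(fit$measure, "OR")
  td <- tidy(fit)
  expect_equal(td$estimate, fit$estimate)
  expect_true(td$ci_low <= td$estimate && td$estimate <= td$ci_high)
  expect_equal(glance(fit)$n_counties, 2L)

  expect_error(fit_exposure_model(mk("A"), "exposed", "x", "logistic"),
               "fewer than 2 counties")
})

test_that("standardized and raw fits are consistent (destandardization round-trip)", {
  set.seed(3)
  n <- 600
  d <- tibble::tibble(
    county_id = rep(c("A", "B", "C"), each = n / 3),
    x = rnorm(n, 5, 2),
    density_km2 = runif(n, 100, 5000))
  d$exposed <- runif(n) < plogis(-1 + 0.3 * (d$x - 5))
  z <- standardize(d, "x")
  f_raw <- fit_exposure_model(d, "exposed", "x", "logistic")
  f_std <- fit_exposure_model(z, "exposed", "x", "logistic")
  s <- unname(attr(z, "scaling")$x["sd"])
  expect_equal(f_std$coef, f_raw$coef * s, tolerance = 1e-6)
  expect_equal(f_std$se_cluster, f_raw$se_cluster * s, tolerance = 1e-6)
})

test_that("count and linear exposure models estimate on the right scales", {
  set.seed(4)
  n <- 900
  d <- tibble::tibble(
    county_id = rep(c("A", "B", "C"), each = n / 3),
    x = rnorm(n),
    density_km2 = runif(n, 100, 5000))
  d$n_sites <- rnbinom(n, mu = exp(0.8 + 0.25 * d$x), size = 3)
  d$eae <- 0.2 + 0.15 * d$x + rnorm(n, 0, 0.3)
  nb <- fit_exposure_model(d, "n_sites", "x", "negbin")
  expect_equal(nb$measure, "IRR")
  expect_equal(log(nb$estimate), 0.25, tolerance = 0.1)
  lin <- fit_exposure_model(d, "eae", "x", "linear")
  expect_equal(lin$measure, "mean_difference")
  expect_equal(lin$estimate, 0.15, tolerance = 0.05)
  # a pure-noise covariate gives OR ~ 1
  d$noise <- rnorm(n)
  d$exposed <- runif(n) < 0.3
  f0 <- fit_exposure_model(d, "exposed", "noise", "logistic")
  expect_lt(abs(log(f0$estimate)), 0.25)
})

test_that("concentration curves and index match hand-built constructions", {
  # equal burden, distinct ranks -> diagonal, C = 0
  cv <- concentration_curve(10:1, rep(2, 10))
  expect_equal(cv$x, cv$y)
  expect_equal(concentration_index(cv), 0)

  # all burden in the top-ranked of 10 -> passes (0.1, 1), C = -0.9
  cv2 <- concentration_curve(10:1, c(5, rep(0, 9)))
  expect_equal(cv2$y[cv2$x == 0.1], 1)
  expect_equal(concentration_index(cv2), -0.9)

  # reversing the ranking flips the sign
  cv3 <- concentration_curve(1:10, c(5, rep(0, 9)))
  expect_equal(concentration_index(cv3), 0.9)

  # y is non-decreasing and ends at 1
  set.seed(5)
  cv4 <- concentration_curve(runif(50), rpois(50, 2) + 0.01)
  expect_true(all(diff(cv4$y) >= -1e-12))
  expect_equal(cv4$y[nrow(cv4)], 1)

  expect_error(concentration_curve(1:5, rep(0, 5)), "all burdens are zero")
})

test_that("concentration index equals the brute-force rank covariance form", {
  # independent formulation: C = 2/(n*T) * sum_j h_j (j - (n+1)/2) with j
  # the descending-rank position
  brute <- function(rank_values, burdens) {
    ord <- order(-rank_values)
    h <- burdens[ord]
    n <- length(h)
    2 / (n * sum(h)) * sum(h * (seq_len(n) - (n + 1) / 2))
  }
  set.seed(6)
  for (k in 1:10) {
    n <- sample(5:20, 1)
    rv <- rnorm(n)
    h <- rgamma(n, 1.5)
    cv <- concentration_curve(rv, h)
    expect_equal(concentration_index(cv), brute(rv, h), tolerance = 1e-9)
  }
})

test_that("tie pooling merges tied ranks into single curve steps", {
  rv <- c(3, 3, 2, 1)
  h <- c(1, 3, 4, 2)
  pooled <- concentration_curve(rv, h, ties = "pool")
  expect_equal(pooled$x, c(0, 0.5, 0.75, 1))
  expect_equal(pooled$y, c(0, 0.4, 0.8, 1))
})

test_that("bootstrap CI for C is deterministic, calibrated and powerful", {
  set.seed(8)
  rv <- rnorm(200)
  h_null <- rep(1, 200)
  ci <- concentration_ci(rv, h_null, n_boot = 300, seed = 9)
  ci_again <- concentration_ci(rv, h_null, n_boot = 300, seed = 9)
  expect_identical(ci, ci_again)
  expect_true(ci$ci_low <= 0 && ci$ci_high >= 0)
  expect_false(ci$significant)

  # extreme concentration: all burden in the top-ranked block groups
  h_conc <- ifelse(rank(-rv) <= 10, 5, 0)
  ci2 <- concentration_ci(rv, h_conc, n_boot = 300, seed = 9)
  expect_true(ci2$ci_high < 0)
  expect_true(ci2$significant)

  expect_error(concentration_ci(rv, h_null, n_boot = 50), "at least 100")
  expect_error(concentration_ci(rv[1:5], h_null[1:5]), "at least 10")
})

test_that("plot functions return ggplot objects", {
  cv <- concentration_curve(10:1, rpois(10, 3) + 0.1)
  expect_s3_class(plot_concentration_curve(cv), "ggplot")
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(plot_return_curve(exp_curve()), "ggplot")
})
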