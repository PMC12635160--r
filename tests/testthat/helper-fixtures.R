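# Shared fixtures, built in code at test time.

# Small region config used across module tests (coarse cells keep rasters
# tiny; the statistical structure is unchanged).
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, extent_m = c(12000, 8000), cell_m = 100,
         n_counties = 4L, n_blockgroups = 40L, slr_samples = 200L),
    list(...))
  do.call(region_config, args)
}

small_region <- local({
  cache <- new.env()
  function(seed = 1L, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (is.null(cache[[key]])) {
      r <- make_region(small_config(seed = seed, ...))
      cache[[key]] <- make_sites_and_demographics(r)
    }
    cache[[key]]
  }
})

# Exponential-tail reference curve (xi = 0).
exp_curve <- function(lambda = 3, mu = 1, sigma = 0.1, cap = 182.6,
                      gauge_id = "G") {
  flood_curve(gauge_id, lambda_rate = lambda, threshold_mu = mu,
              scale_sigma = sigma, shape_xi = 0, cap_rate = cap)
}

# Unit square polygon helper.
square <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

# A raw-record tibble row with sensible defaults.
raw_record <- function(record_id = "R1", address = "12 Harbor St",
                       x = 100, y = 100, program = "TRI", naics = "3251",
                       keyword = NA_character_, active = TRUE,
                       end_date = NA_integer_, accuracy_m = 10,
                       geometry = list(NULL), category = NULL) {
  out <- tibble::tibble(record_id = record_id, source = "FRS",
                        address = address, x = x, y = y, program = program,
                        naics = naics, keyword = keyword, active = active,
                        end_date = end_date, accuracy_m = accuracy_m,
                        geometry = geometry)
  if (!is.null(category)) out$category <- category
  out
}
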