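# Summary surfaces: at-risk counts and percentages by category and
# scenario-year, scenario comparisons, category shares, and the end-to-end
# pipeline orchestrator.

#' Decimal half-up rounding
#'
#' Rounds halves away from zero at the given number of decimals (matching
#' conventional table formatting rather than banker's rounding).
#' @param x numeric
#' @param digits decimal places
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Category summary of at-risk sites across scenario-years
#'
#' Counts and one-decimal percentages of at-risk sites per category for each
#' scenario x year in the input, plus a grand-total row. The input must be a
#' valid partition: a site appearing under two categories is an error.
#'
#' @param site_risk_tables one tibble (rows from [site_risk_table()] for all
#'   scenario-year combinations, bound together) or a list of such tibbles
#' @return tibble: category, total, then `<scenario>_<year>_n` /
#'   `<scenario>_<year>_pct` column pairs
#' @export
summarize_by_category <- function(site_risk_tables) {
  risk <- if (is.data.frame(site_risk_tables)) site_risk_tables else
    dplyr::bind_rows(site_risk_tables)
  cat_of <- unique(risk[, c("site_id", "category")])
  if (anyDuplicated(cat_of$site_id)) {
    dup <- cat_of$site_id[duplicated(cat_of$site_id)][1]
    stop(sprintf("site %s appears in more than one category: partition violated", dup))
  }
  combos <- unique(risk[, c("scenario", "year")])
  combos <- combos[order(combos$scenario, combos$year), ]
  cats <- unique(cat_of$category)
  totals <- table(factor(cat_of$category, levels = cats))

  out <- tibble::tibble(category = cats, total = as.integer(totals[cats]))
  for (k in seq_len(nrow(combos))) {
    sub <- risk[risk$scenario == combos$scenario[k] & risk$year == combos$year[k], ]
    atr <- table(factor(sub$category[sub$at_risk], levels = cats))
    nm <- sprintf("%s_%d", tolower(combos$scenario[k]), combos$year[k])
    out[[paste0(nm, "_n")]] <- as.integer(atr[cats])
    out[[paste0(nm, "_pct")]] <- round_half_up(100 * as.integer(atr[cats]) /
                                                 out$total, 1)
  }
  tot_row <- tibble::tibble(category = "total", total = sum(out$total))
  for (k in seq_len(nrow(combos))) {
    nm <- sprintf("%s_%d", tolower(combos$scenario[k]), combos$year[k])
    n <- sum(out[[paste0(nm, "_n")]])
    tot_row[[paste0(nm, "_n")]] <- n
    tot_row[[paste0(nm, "_pct")]] <- round_half_up(100 * n / tot_row$total, 1)
  }
  dplyr::bind_rows(out, tot_row)
}

#' Difference between two scenario at-risk counts
#'
#' @param count_a at-risk count under the larger (high-emissions) scenario
#' @param count_b at-risk count under the comparison scenario
#' @return list: `absolute` reduction, `percent` of the larger count
#'   (integer-rounded), and `percent_of_smaller` for reference
#' @export
scenario_difference <- function(count_a, count_b) {
  stopifnot(count_a >= 0, count_b >= 0)
  d <- count_a - count_b
  list(absolute = d,
       percent = round_half_up(100 * d / max(count_a, count_b), 0),
       percent_of_smaller = round_half_up(100 * d / min(count_a, count_b), 0))
}

#' Category share of the total at-risk count
#'
#' @param category_count at-risk count in the category (or sum of
#'   categories)
#' @param total_at_risk total at-risk count (> 0)
#' @return integer-rounded percentage
#' @export
share_of_total <- function(category_count, total_at_risk) {
  if (total_at_risk <= 0) stop("total at-risk count must be positive")
  round_half_up(100 * category_count / total_at_risk, 0)
}

## ---- pipeline ------------------------------------------------------------

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

write_csv_stable <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
}

#' Run the full hazard-equity pipeline on a synthetic region
#'
#' Generates (or loads) a region, cleans sites, computes flood risk for
#' every scenario-year, block-group exposure at 1 km and 3 km, equity
#' statistics, and category summaries; writes CSV outputs, a JSON manifest
#' and a plain-text log into `out_dir`.
#'
#' @param config a [region_config()], or a path to a fixture bundle written
#'   by [write_fixture_bundle()]
#' @param out_dir output directory (created if missing)
#' @param covariates covariates for the equity stage (default: the region's
#'   association covariate plus renters, people of color and the CEJST flag)
#' @param n_boot bootstrap replicates for concentration CIs
#' @return invisibly, a list of the in-memory stage outputs
#' @export
run_pipeline <- function(config, out_dir, covariates = NULL, n_boot = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  say <- function(...) writeLines(sprintf(...), logcon)

  region <- pipeline_stage("synth", {
    if (inherits(config, "region_config")) {
      r <- make_region(config)
      make_sites_and_demographics(r)
    } else if (is.character(config)) {
      read_fixture_bundle(config)
    } else stop("config must be a region_config or a fixture directory")
  })
  say("synth: %d raw records, %d block groups, %d counties, popgrid: %s",
      nrow(region$raw_sites), nrow(region$blockgroups), nrow(region$counties),
      if (is.null(region$popgrid)) "absent (block-group fallback mode)" else "present")

  sites <- pipeline_stage("ingest", {
    ingest_sites(region$raw_sites, region$parcels, region$land,
                 region$blockgroups, region$dem, region$gauges)
  })
  for (i in seq_len(nrow(exclusion_log(sites)))) {
    lg <- exclusion_log(sites)[i, ]
    say("ingest exclusion [%s] %s: %d", lg$stage, lg$rule, lg$n)
  }
  say("ingest: %d cleaned sites", nrow(sites))
  write_csv_stable(sites[, c("site_id", "category", "provenance",
                             "elevation_q25", "gauge_id")],
                   file.path(out_dir, "sites.csv"))
  write_csv_stable(exclusion_log(sites), file.path(out_dir, "exclusions.csv"))

  curves <- flood_curves_tbl(region$gauges)
  combos <- expand.grid(scenario = c("RCP45", "RCP85"), year = c(2050, 2100),
                        stringsAsFactors = FALSE)
  risk <- pipeline_stage("floodrisk", {
    purrr::pmap(combos, function(scenario, year) {
      site_risk_table(sites, region$slr, curves, scenario, year)
    })
  })
  risk_all <- dplyr::bind_rows(risk)
  write_csv_stable(risk_all, file.path(out_dir, "site_risk.csv"))
  say("floodrisk: %d site x scenario-year rows, %d at risk",
      nrow(risk_all), sum(risk_all$at_risk))

  exposure <- pipeline_stage("exposure", {
    r85_2100 <- risk_all[risk_all$scenario == "RCP85" & risk_all$year == 2100, ]
    study <- select_study_counties(region$counties, r85_2100, sites)
    coastal <- select_coastal_blockgroups(region$blockgroups, region$dem, study)
    bgs <- region$blockgroups[region$blockgroups$bg_id %in% coastal, ]
    tabs <- list()
    for (k in seq_len(nrow(combos))) for (rad in c(1000, 3000)) {
      rt <- risk_all[risk_all$scenario == combos$scenario[k] &
                       risk_all$year == combos$year[k], ]
      tabs[[length(tabs) + 1L]] <- exposure_table(bgs, sites, rt, rad,
                                                  popgrid = region$popgrid)
    }
    list(study_counties = study, coastal_bg = coastal,
         table = dplyr::bind_rows(tabs), universe = bgs)
  })
  write_csv_stable(exposure$table, file.path(out_dir, "exposure.csv"))
  say("exposure: %d study counties, %d coastal block groups",
      length(exposure$study_counties), length(exposure$coastal_bg))

  equity <- pipeline_stage("equity", {
    if (is.null(covariates)) {
      covariates <- unique(c(region$truth$assoc$covariate,
                             "p_renters", "p_poc", "cejst_disadvantaged"))
    }
    uni <- exposure$universe
    expo_main <- exposure$table[exposure$table$scenario == "RCP85" &
                                  exposure$table$year == 2100 &
                                  exposure$table$radius_m == 1000, ]
    df <- dplyr::left_join(uni, expo_main, by = c("bg_id", "county_id"))
    dfz <- standardize(df, setdiff(covariates, "cejst_disadvantaged"))
    ests <- list(); conc <- list()
    for (cv in covariates) {
      fit <- tryCatch(
        fit_exposure_model(dfz, "exposed", cv, "logistic"),
        error = function(e) { say("equity: logistic %s skipped: %s", cv,
                                  conditionMessage(e)); NULL })
      if (!is.null(fit)) ests[[length(ests) + 1L]] <- tidy(fit)
      ci <- tryCatch(
        concentration_ci(df[[cv]], df$n_sites, n_boot = n_boot,
                         seed = region$config$seed + 7L),
        error = function(e) NULL)
      if (!is.null(ci)) {
        conc[[length(conc) + 1L]] <- tibble::tibble(
          covariate = cv, burden = "n_sites", index = ci$index,
          ci_low = ci$ci_low, ci_high = ci$ci_high,
          significant = ci$significant)
      }
    }
    list(estimates = dplyr::bind_rows(ests),
         concentration = dplyr::bind_rows(conc),
         comparison = compare_exposed_unexposed(df, covariates))
  })
  write_csv_stable(equity$estimates, file.path(out_dir, "estimates.csv"))
  write_csv_stable(equity$concentration, file.path(out_dir, "concentration.csv"))
  write_csv_stable(equity$comparison, file.path(out_dir, "group_comparison.csv"))

  report <- pipeline_stage("report", {
    tab1 <- summarize_by_category(risk_all)
    tot <- tab1[tab1$category == "total", ]
    diff2100 <- scenario_difference(tot$rcp85_2100_n, tot$rcp45_2100_n)
    list(table1 = tab1, diff2100 = diff2100)
  })
  write_csv_stable(report$table1, file.path(out_dir, "table1.csv"))

  manifest <- list(
    seed = region$config$seed,
    generated = !is.character(config),
    popgrid_fallback = is.null(region$popgrid),
    stages = list(
      synth = list(raw_records = nrow(region$raw_sites),
                   blockgroups = nrow(region$blockgroups)),
      ingest = list(sites = nrow(sites)),
      floodrisk = list(rows = nrow(risk_all), at_risk = sum(risk_all$at_risk)),
      exposure = list(study_counties = length(exposure$study_counties),
                      coastal_blockgroups = length(exposure$coastal_bg),
                      rows = nrow(exposure$table)),
      equity = list(estimates = nrow(equity$estimates),
                    concentration = nrow(equity$concentration))
    ))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("report: total at risk RCP85 2100 = %d; reduction vs RCP45 = %d (%d%%)",
      report$table1$rcp85_2100_n[report$table1$category == "total"],
      report$diff2100$absolute, report$diff2100$percent)

  invisible(list(region = region, sites = sites, risk = risk_all,
                 exposure = exposure, equity = equity, report = report))
}
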