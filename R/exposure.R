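# Analysis universe and block-group exposure outcomes.
#
# The study universe is restricted to counties with at least one at-risk
# site under RCP8.5 by 2100, and within them to "coastal" block groups: those
# within 3 km Euclidean distance of the land at or below the 10 m elevation
# contour above MHHW. Exposure outcomes are measured from the populated
# portion of each block group (30 m population-grid cells with people in
# them; the whole polygon where no grid is available) to the nearest point
# of each at-risk site's footprint.

#' Select study counties
#'
#' Counties retained are those containing at least one at-risk site in the
#' reference risk table (conventionally RCP8.5, 2100).
#'
#' @param counties county tibble (`county_id`, `geometry`)
#' @param site_risk risk table from [site_risk_table()]
#' @param sites cleaned sites (to locate each site's footprint centroid)
#' @return character vector of retained county ids
#' @export
select_study_counties <- function(counties, site_risk, sites) {
  risky <- site_risk$site_id[site_risk$at_risk]
  if (length(risky) == 0) return(character(0))
  idx <- match(risky, sites$site_id)
  ctr <- t(vapply(sites$footprint[idx], fp_centroid, numeric(2)))
  keep <- vapply(seq_len(nrow(counties)), function(i) {
    g <- counties$geometry[[i]]
    any(sp::point.in.polygon(ctr[, 1], ctr[, 2], g[, 1], g[, 2]) > 0)
  }, logical(1))
  counties$county_id[keep]
}

#' Select coastal block groups
#'
#' Retains block groups (within the study counties) lying within
#' `buffer_m` of the land at or below the `contour_m` elevation contour:
#' the sub-contour zone itself plus a Euclidean fringe around it, derived
#' from DEM cells below the contour.
#'
#' @param blockgroups block-group tibble
#' @param dem elevation [grid_raster()]
#' @param study_counties county ids from [select_study_counties()]
#' @param contour_m elevation contour (default 10 m above MHHW)
#' @param buffer_m Euclidean buffer distance (default 3000 m)
#' @return character vector of retained bg ids
#' @export
select_coastal_blockgroups <- function(blockgroups, dem, study_counties,
                                       contour_m = 10, buffer_m = 3000) {
  low <- which(as.vector(dem$values) < contour_m & !is.na(as.vector(dem$values)))
  if (length(low) == 0) {
    stop(sprintf("DEM has no cells below %g m: no coastal zone", contour_m))
  }
  centers <- raster_centers(dem)[low, , drop = FALSE]
  in_study <- blockgroups$county_id %in% study_counties
  keep <- logical(nrow(blockgroups))
  for (i in which(in_study)) {
    g <- blockgroups$geometry[[i]]
    bx <- range(g[, 1]); by <- range(g[, 2])
    cand <- centers[, 1] >= bx[1] - buffer_m & centers[, 1] <= bx[2] + buffer_m &
      centers[, 2] >= by[1] - buffer_m & centers[, 2] <= by[2] + buffer_m
    if (!any(cand)) next
    p <- centers[cand, , drop = FALSE]
    d <- dist_points_fp(p, as_footprint(g))
    keep[i] <- any(d <= buffer_m)
  }
  blockgroups$bg_id[keep]
}

#' Populated portion of a block group
#'
#' Centers of population-grid cells with population > 0 whose centers fall
#' inside the polygon. With `popgrid = NULL` (fallback where gridded
#' population is unavailable) the polygon itself is the populated geometry.
#'
#' @param geometry block-group polygon (vertex matrix)
#' @param popgrid population [grid_raster()] or `NULL`
#' @return list with `mode` ("cells" or "polygon") and `centers` (matrix)
#'   or `polygon`
#' @export
populated_cells <- function(geometry, popgrid = NULL) {
  if (is.null(popgrid)) {
    return(list(mode = "polygon", polygon = geometry))
  }
  cells <- raster_cells_in_fp(popgrid, as_footprint(geometry))
  keep <- !is.na(cells$values) & cells$values > 0
  list(mode = "cells", centers = cells$centers[keep, , drop = FALSE])
}

# Minimum distance from a populated geometry to a site footprint.
dist_populated_fp <- function(popd, fp) {
  if (popd$mode == "cells") {
    if (nrow(popd$centers) == 0) return(Inf)
    min(dist_points_fp(popd$centers, fp))
  } else {
    dist_fp_fp(as_footprint(popd$polygon), fp)
  }
}

#' Exposure outcomes for one block group
#'
#' Counts at-risk sites whose footprint lies within `radius_m` of the block
#' group's populated geometry (each site at most once), flags exposure, and
#' sums their annual flood probabilities into the expected annual exposure
#' (EAE).
#'
#' @param geometry block-group polygon
#' @param at_risk_sites tibble of at-risk sites with `footprint` and
#'   `p_annual`
#' @param radius_m proximity radius (1000 or 3000 m in the main analyses)
#' @param popgrid population [grid_raster()] or `NULL` for fallback mode
#' @return list with `exposed`, `n_sites`, `eae`
#' @export
blockgroup_exposure <- function(geometry, at_risk_sites, radius_m = 1000,
                                popgrid = NULL) {
  popd <- populated_cells(geometry, popgrid)
  if (popd$mode == "cells" && nrow(popd$centers) == 0) {
    return(list(exposed = FALSE, n_sites = 0L, eae = 0))
  }
  bb <- fp_bbox(as_footprint(geometry))
  hit <- logical(nrow(at_risk_sites))
  for (j in seq_len(nrow(at_risk_sites))) {
    fp <- at_risk_sites$footprint[[j]]
    if (bbox_gap(bb, fp_bbox(fp)) > radius_m) next
    hit[j] <- dist_populated_fp(popd, fp) <= radius_m
  }
  list(exposed = any(hit), n_sites = sum(hit),
       eae = sum(at_risk_sites$p_annual[hit]))
}

#' Block-group exposure table for one scenario, year and radius
#'
#' @param blockgroups block-group tibble (optionally pre-restricted to the
#'   coastal universe)
#' @param sites cleaned sites with `footprint`
#' @param site_risk risk table for one scenario and year
#' @param radius_m proximity radius in meters
#' @param popgrid population [grid_raster()] or `NULL`
#' @param at_risk_only sum EAE over at-risk sites only (default `TRUE`)
#' @return tibble: bg_id, county_id, scenario, year, radius_m, exposed,
#'   n_sites, eae
#' @export
exposure_table <- function(blockgroups, sites, site_risk, radius_m = 1000,
                           popgrid = NULL, at_risk_only = TRUE) {
  rs <- if (at_risk_only) site_risk[site_risk$at_risk, , drop = FALSE] else site_risk
  idx <- match(rs$site_id, sites$site_id)
  stopifnot(!anyNA(idx))
  risk_sites <- tibble::tibble(site_id = rs$site_id,
                               footprint = sites$footprint[idx],
                               p_annual = rs$p_annual)
  scen <- if (nrow(site_risk)) site_risk$scenario[1] else NA_character_
  yr <- if (nrow(site_risk)) site_risk$year[1] else NA_integer_

  n_bg <- nrow(blockgroups)
  ns <- nrow(risk_sites)
  n_hit <- integer(n_bg); eae <- numeric(n_bg)
  if (ns > 0) {
    sb <- t(vapply(risk_sites$footprint, fp_bbox, numeric(4)))
    r2 <- radius_m^2
    for (i in seq_len(n_bg)) {
      g <- blockgroups$geometry[[i]]
      bx0 <- min(g[, 1]); bx1 <- max(g[, 1])
      by0 <- min(g[, 2]); by1 <- max(g[, 2])
      dx <- pmax(bx0 - sb[, 3], sb[, 1] - bx1, 0)
      dy <- pmax(by0 - sb[, 4], sb[, 2] - by1, 0)
      cand <- which(dx * dx + dy * dy <= r2)
      if (length(cand) == 0) next
      popd <- populated_cells(g, popgrid)
      if (popd$mode == "cells" && nrow(popd$centers) == 0) next
      hit <- vapply(cand, function(j) {
        dist_populated_fp(popd, risk_sites$footprint[[j]]) <= radius_m
      }, logical(1))
      n_hit[i] <- sum(hit)
      eae[i] <- sum(risk_sites$p_annual[cand[hit]])
    }
  }
  tibble::tibble(
    bg_id = blockgroups$bg_id,
    county_id = blockgroups$county_id,
    scenario = scen, year = yr, radius_m = radius_m,
    exposed = n_hit >= 1L, n_sites = n_hit, eae = eae)
}
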