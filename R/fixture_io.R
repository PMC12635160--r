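# Writing and reading synthetic regions as interchange files: GeoJSON for
# vectors, ESRI ASCII grids for rasters, CSV for tables, JSON for the
# manifest and generative truth. Coordinates are on the region's local
# planar CRS in meters.

close_ring <- function(p) rbind(p, p[1, , drop = FALSE])

geojson_feature <- function(geom, type, props) {
  coords <- switch(type,
    Polygon = list(apply(close_ring(geom), 1, as.list, simplify = FALSE)),
    LineString = apply(geom, 1, as.list, simplify = FALSE))
  list(type = "Feature",
       geometry = list(type = type, coordinates = coords),
       properties = as.list(props))
}

write_geojson <- function(tbl, path, geometry_col = "geometry",
                          type = "Polygon") {
  prop_cols <- setdiff(names(tbl), geometry_col)
  prop_cols <- prop_cols[!vapply(tbl[prop_cols], is.list, logical(1))]
  feats <- purrr::map(seq_len(nrow(tbl)), function(i) {
    geojson_feature(tbl[[geometry_col]][[i]], type,
                    as.list(tbl[i, prop_cols, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "urn:local:planar-meters")),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- fc$features
  geoms <- purrr::map(feats, function(f) {
    cc <- f$geometry$coordinates
    if (f$geometry$type == "Polygon") cc <- cc[[1]]
    m <- do.call(rbind, purrr::map(cc, ~ c(.x[[1]], .x[[2]])))
    if (f$geometry$type == "Polygon") m <- m[-nrow(m), , drop = FALSE]  # unclose
    m
  })
  props <- purrr::map(feats, function(f) {
    p <- f$properties
    p[vapply(p, is.null, logical(1))] <- NA
    tibble::as_tibble(p)
  })
  out <- dplyr::bind_rows(props)
  if (nrow(out) == 0) out <- tibble::tibble(.rows = length(geoms))
  out$geometry <- geoms
  out
}

#' Write a synthetic region as a fixture bundle
#'
#' Vectors go to GeoJSON, rasters to plain-text ESRI ASCII grids, site and
#' SLR tables to CSV, and the generative truth plus a manifest (layer paths,
#' seed, CRS) to JSON. [read_fixture_bundle()] reproduces the region.
#'
#' @param region a complete `synthetic_region`
#' @param directory output directory (created if missing)
#' @return the manifest, invisibly
#' @export
write_fixture_bundle <- function(region, directory) {
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  pth <- function(f) file.path(directory, f)

  write_ascii_grid(region$dem, pth("dem.asc"))
  layers <- list(dem = "dem.asc")
  if (!is.null(region$popgrid)) {
    write_ascii_grid(region$popgrid, pth("popgrid.asc"))
    layers$popgrid <- "popgrid.asc"
  }

  write_geojson(region$counties, pth("counties.geojson"))
  write_geojson(region$blockgroups, pth("blockgroups.geojson"))
  write_geojson(region$parcels, pth("parcels.geojson"))
  write_geojson(tibble::tibble(name = "coastline",
                               geometry = list(region$coastline)),
                pth("coastline.geojson"), type = "LineString")
  layers <- c(layers, counties = "counties.geojson",
              blockgroups = "blockgroups.geojson",
              parcels = "parcels.geojson", coastline = "coastline.geojson")

  raw <- region$raw_sites
  has_poly <- !vapply(raw$geometry, is.null, logical(1))
  utils::write.csv(raw[, setdiff(names(raw), "geometry")],
                   pth("raw_sites.csv"), row.names = FALSE)
  layers$raw_sites <- "raw_sites.csv"
  if (any(has_poly)) {
    write_geojson(raw[has_poly, c("record_id", "geometry")],
                  pth("fuds_polygons.geojson"))
    layers$fuds_polygons <- "fuds_polygons.geojson"
  }

  utils::write.csv(region$gauges, pth("gauges.csv"), row.names = FALSE)
  layers$gauges <- "gauges.csv"
  slr_long <- tidyr::unnest(
    dplyr::mutate(region$slr,
                  sample_index = purrr::map(samples, seq_along)),
    cols = c("samples", "sample_index"))
  slr_long <- slr_long[, c("gauge_id", "scenario", "year", "sample_index",
                           "samples")]
  names(slr_long)[5] <- "value_m"
  utils::write.csv(slr_long, pth("slr_samples.csv"), row.names = FALSE)
  layers$slr <- "slr_samples.csv"

  truth <- region$truth
  jsonlite::write_json(truth, pth("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  layers$truth <- "truth.json"

  cfg <- unclass(region$config)
  manifest <- list(seed = region$config$seed,
                   crs = "local planar CRS, units = meters",
                   config = cfg, layers = layers)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture bundle back into a synthetic region
#'
#' @param directory directory written by [write_fixture_bundle()]
#' @return a `synthetic_region`
#' @export
read_fixture_bundle <- function(directory) {
  pth <- function(f) file.path(directory, f)
  manifest <- jsonlite::read_json(pth("manifest.json"), simplifyVector = TRUE)
  cfg <- manifest$config
  cfg$extent_m <- as.numeric(cfg$extent_m)
  cfg$n_sites_per_category <- unlist(cfg$n_sites_per_category)
  config <- do.call(region_config, cfg[intersect(names(cfg),
                                                 names(formals(region_config)))])

  dem <- read_ascii_grid(pth(manifest$layers$dem))
  popgrid <- if (!is.null(manifest$layers$popgrid)) {
    read_ascii_grid(pth(manifest$layers$popgrid))
  } else NULL

  counties <- read_geojson(pth(manifest$layers$counties))
  blockgroups <- read_geojson(pth(manifest$layers$blockgroups))
  parcels <- read_geojson(pth(manifest$layers$parcels))
  coastline <- read_geojson(pth(manifest$layers$coastline))$geometry[[1]]

  raw <- tibble::as_tibble(utils::read.csv(pth(manifest$layers$raw_sites),
                                           stringsAsFactors = FALSE))
  raw$geometry <- vector("list", nrow(raw))
  if (!is.null(manifest$layers$fuds_polygons)) {
    fp <- read_geojson(pth(manifest$layers$fuds_polygons))
    raw$geometry[match(fp$record_id, raw$record_id)] <- fp$geometry
  }

  gauges <- tibble::as_tibble(utils::read.csv(pth(manifest$layers$gauges),
                                              stringsAsFactors = FALSE))
  slr_long <- utils::read.csv(pth(manifest$layers$slr), stringsAsFactors = FALSE)
  slr <- dplyr::summarise(
    dplyr::group_by(slr_long, .data$gauge_id, .data$scenario, .data$year),
    samples = list(.data$value_m[order(.data$sample_index)]),
    median_m = stats::median(.data$value_m), .groups = "drop")
  slr$year <- as.integer(slr$year)

  truth <- jsonlite::read_json(pth(manifest$layers$truth), simplifyVector = TRUE)
  if (!is.null(truth$site_risk)) truth$site_risk <- tibble::as_tibble(truth$site_risk)
  if (!is.null(truth$bg_exposed)) truth$bg_exposed <- tibble::as_tibble(truth$bg_exposed)

  W <- ncol(dem$values) * dem$cell; H <- nrow(dem$values) * dem$cell
  structure(list(config = config, land = rect_polygon(0, 0, W, H),
                 coastline = coastline, dem = dem, counties = counties,
                 blockgroups = blockgroups, popgrid = popgrid,
                 gauges = gauges, slr = slr, parcels = parcels,
                 raw_sites = raw, truth = truth),
            class = "synthetic_region")
}
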