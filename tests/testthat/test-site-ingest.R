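test_that("filtering drops imprecise and closed records but keeps inactive ones", {
  recs <- dplyr::bind_rows(
    raw_record("R1", accuracy_m = 60),                       # imprecise
    raw_record("R2", accuracy_m = 10, active = FALSE),       # inactive, kept
    raw_record("R3", end_date = 2019L),                      # closed
    raw_record("R4", end_date = 2021L),                      # still regulated
    raw_record("R5", accuracy_m = 50))                       # exactly at cutoff
  out <- filter_records(recs)
  expect_setequal(out$record_id, c("R2", "R4", "R5"))
  lg <- exclusion_log(out)
  expect_equal(sum(lg$n), 2)

  empty <- filter_records(recs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("categorization assigns one category by rule priority", {
  recs <- dplyr::bind_rows(
    # refinery NAICS plus a generic discharge permit: specific rule wins
    raw_record("R1", program = "NPDES", naics = "32411"),
    raw_record("R2", program = "POTW", naics = NA),
    raw_record("R3", program = NA, naics = NA, keyword = "landfill"),
    raw_record("R4", program = NA, naics = NA, keyword = NA))  # no rule
  out <- categorize(recs)
  expect_equal(out$category[out$record_id == "R1"], "refinery")
  expect_equal(out$category[out$record_id == "R2"], "sewage_treatment")
  expect_equal(out$category[out$record_id == "R3"], "solid_waste")
  expect_false("R4" %in% out$record_id)
  expect_equal(exclusion_log(out)$n[exclusion_log(out)$rule == "no matching rule"], 1)
  # exactly one category per record
  expect_equal(sum(table(out$record_id) > 1), 0)

  # two distinct rules at equal priority matching one record is a
  # configuration error
  bad_rules <- tibble::tibble(category = c("refinery", "power_plant"),
                              field = c("program", "program"),
                              pattern = c("XX", "XX"), priority = c(1L, 1L))
  expect_error(categorize(raw_record("R9", program = "XX"), bad_rules),
               "equal priority")
})

test_that("address similarity matches a normalized-indel oracle", {
  # independent oracle: similarity = 1 - (n1 + n2 - 2 LCS) / (n1 + n2)
  lcs <- function(a, b) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    d <- matrix(0L, length(a) + 1, length(b) + 1)
    for (i in seq_along(a)) for (j in seq_along(b)) {
      d[i + 1, j + 1] <- if (a[i] == b[j]) d[i, j] + 1L else
        max(d[i, j + 1], d[i + 1, j])
    }
    d[length(a) + 1, length(b) + 1]
  }
  norm <- function(s) gsub("\\s+", " ", trimws(gsub("[[:punct:]]", " ", toupper(s))))
  oracle <- function(a, b) {
    a <- norm(a); b <- norm(b)
    1 - (nchar(a) + nchar(b) - 2 * lcs(a, b)) / (nchar(a) + nchar(b))
  }
  pairs <- list(c("123 Main St", "123 Main Street"),
                c("1 Ocean Rd", "987 Mountain Ave"),
                c("45 Pier Ln", "45 PIER LN"),
                c("700 Cannery Blvd.", "700 Canery Blvd"),
                c("8 Dune Way", "8 Dune Way"))
  for (p in pairs) {
    expect_equal(address_similarity(p[1], p[2]), oracle(p[1], p[2]),
                 tolerance = 1e-12, label = paste(p, collapse = " / "))
  }
  expect_gte(address_similarity("123 Main St", "123 Main Street"), 0.8)
  expect_lt(address_similarity("1 Ocean Rd", "987 Mountain Ave"), 0.8)
})

test_that("deduplication collapses, retains and flags as specified", {
  recs <- dplyr::bind_rows(
    raw_record("A1", "123 Main St", x = 10, y = 10, category = "tri_industrial"),
    raw_record("A2", "123 Main Street", x = 10, y = 10, category = "tri_industrial"),
    # identical coordinates, similar addresses, different categories: both kept
    raw_record("B1", "9 Pier Ln", x = 20, y = 20, category = "refinery"),
    raw_record("B2", "9 Pier Lane", x = 20, y = 20, category = "fossil_port_terminal"),
    # identical coordinates, dissimilar addresses: flagged
    raw_record("C1", "1 Ocean Rd", x = 30, y = 30, category = "solid_waste"),
    raw_record("C2", "987 Mountain Ave", x = 30, y = 30, category = "solid_waste"))
  out <- dedupe(recs)
  expect_setequal(out$record_id, c("A1", "B1", "B2"))
  expect_equal(nrow(attr(out, "flagged")), 2)

  # a plausibility predicate that accepts keeps one record per address cluster
  out2 <- dedupe(recs, implausible = function(grp) FALSE)
  expect_true(all(c("C1", "C2") %in% out2$record_id))

  # idempotence: dedupe of its own output changes nothing
  out3 <- dedupe(out)
  strip <- function(x) { attr(x, "exclusions") <- NULL; attr(x, "flagged") <- NULL; x }
  expect_identical(strip(out3), strip(out))
})

test_that("footprints come from parcels, median-area buffers, or points", {
  # parcel of area pi around the first record; second record of the same
  # category intersects nothing -> buffer radius sqrt(A_med/pi) = 1
  parcels <- tibble::tibble(
    parcel_id = "P1",
    geometry = list(cbind(c(-1, 1, 1, -1) * sqrt(pi) / 2 + 100,
                          c(-1, -1, 1, 1) * sqrt(pi) / 2 + 100)))
  recs <- dplyr::bind_rows(
    raw_record("R1", x = 100, y = 100, category = "tri_industrial"),
    raw_record("R2", x = 500, y = 500, category = "tri_industrial"),
    raw_record("W1", x = 300, y = 300, program = "WELL", naics = "2111",
               category = "oil_gas_well"))
  out <- assign_footprint(recs, parcels)
  expect_equal(out$provenance, c("parcel", "buffer", "point"))
  expect_equal(floodequity:::fp_area(out$footprint[[1]]), pi, tolerance = 1e-9)
  # buffer radius 1 m around (500, 500)
  verts <- out$footprint[[2]][[1]]
  expect_equal(sqrt((verts[, 1] - 500)^2 + (verts[, 2] - 500)^2),
               rep(1, nrow(verts)), tolerance = 1e-9)
  expect_true(floodequity:::fp_is_point(out$footprint[[3]]))

  # a category with no parcel hits and no fallback area errors by name
  lone <- raw_record("R3", x = 900, y = 900, category = "refinery")
  expect_error(assign_footprint(lone, parcels), "refinery")
  ok <- assign_footprint(lone, parcels, category_median_areas = c(refinery = pi))
  expect_equal(ok$provenance, "buffer")
})

test_that("FUDS overlap rules split at 0.40, merge at 0.50, flag triples", {
  fuds_rec <- function(id, geom = NULL, x = 0, y = 0) {
    r <- raw_record(id, x = x, y = y, program = "FUDS", naics = NA,
                    category = "fuds")
    r$geometry <- list(geom)
    r
  }
  A <- square(0, 0, 10); B40 <- square(6, 0, 10)   # overlap 40 / min area 100
  out <- resolve_fuds(dplyr::bind_rows(fuds_rec("A", A), fuds_rec("B", B40)))
  expect_equal(nrow(out), 2)
  a1 <- floodequity:::fp_area(out$footprint[[1]])
  a2 <- floodequity:::fp_area(out$footprint[[2]])
  # split preserves total area and halves the overlap between the two
  expect_equal(a1 + a2, 160, tolerance = 1e-6)
  expect_equal(a1, 80, tolerance = 1e-6)
  expect_lt(floodequity:::fp_intersection_area(out$footprint[[1]],
                                               out$footprint[[2]]), 1e-6)

  B50 <- square(5, 0, 10)                          # overlap 50 -> merge
  out2 <- resolve_fuds(dplyr::bind_rows(fuds_rec("A", A), fuds_rec("B", B50)))
  expect_equal(nrow(out2), 1)
  expect_equal(out2$site_id, "A+B")
  expect_equal(floodequity:::fp_area(out2$footprint[[1]]), 150, tolerance = 1e-6)

  # chain of three overlapping polygons: flagged unresolved, excluded
  C <- square(12, 0, 10)
  out3 <- resolve_fuds(dplyr::bind_rows(fuds_rec("A", A), fuds_rec("B", B40),
                                        fuds_rec("C", C)))
  expect_equal(nrow(out3), 0)
  expect_setequal(attr(out3, "unresolved")$record_id, c("A", "B", "C"))

  # points: inside a polygon -> dropped; outside -> median-area buffer;
  # buffer overlapping a polygon -> clipped by it
  out4 <- resolve_fuds(dplyr::bind_rows(
    fuds_rec("A", A), fuds_rec("Pin", x = 5, y = 5),
    fuds_rec("Pout", x = 60, y = 60), fuds_rec("Pnear", x = 13, y = 5)))
  expect_false("Pin" %in% out4$site_id)
  buf <- out4$footprint[[which(out4$site_id == "Pout")]]
  expect_equal(floodequity:::fp_area(buf), 100, tolerance = 0.5)  # median polygon area
  near <- out4$footprint[[which(out4$site_id == "Pnear")]]
  expect_lt(floodequity:::fp_area(near), 100)
  expect_lt(floodequity:::fp_intersection_area(near, out4$footprint[[1]]), 1e-6)
})

test_that("coastline clipping and offshore-well exclusion behave at boundaries", {
  land <- square(0, 0, 100)
  sites <- tibble::tibble(
    site_id = c("in", "straddle", "out", "well_off"),
    category = c("tri_industrial", "tri_industrial", "tri_industrial",
                 "oil_gas_well"),
    footprint = list(floodequity:::as_footprint(square(10, 10, 5)),
                     floodequity:::as_footprint(square(-5, 10, 10)),
                     floodequity:::as_footprint(square(-30, 10, 5)),
                     floodequity:::point_footprint(-10, 50)),
    provenance = c("parcel", "buffer", "buffer", "point"),
    x = c(12, 0, -27, -10), y = c(12, 15, 12, 50))
  out <- clip_to_coast(sites, land)
  expect_setequal(out$site_id, c("in", "straddle", "well_off"))
  expect_equal(floodequity:::fp_area(out$footprint[[which(out$site_id == "in")]]), 25)
  expect_equal(floodequity:::fp_area(out$footprint[[which(out$site_id == "straddle")]]),
               50, tolerance = 1e-9)

  bgs <- tibble::tibble(bg_id = "B1", geometry = list(square(0, 0, 100)))
  wells <- tibble::tibble(
    site_id = c("on", "off", "edge"),
    category = "oil_gas_well",
    footprint = list(floodequity:::point_footprint(50, 50),
                     floodequity:::point_footprint(-10, 50),
                     floodequity:::point_footprint(0, 50)),
    provenance = "point", x = c(50, -10, 0), y = c(50, 50, 50))
  kept <- exclude_offshore_wells(wells, bgs)
  # boundary-inclusive: the well exactly on the boundary is covered
  expect_setequal(kept$site_id, c("on", "edge"))
})

test_that("site elevation is the interpolated 25th percentile of covered cells", {
  dem <- grid_raster(matrix(c(1, 3, 2, 4), 2, 2), xmin = 0, ymin = 0, cell = 1)
  sites <- tibble::tibble(
    site_id = "S1", category = "tri_industrial",
    footprint = list(floodequity:::as_footprint(square(0, 0, 2))),
    provenance = "parcel", x = 1, y = 1)
  out <- site_elevation(sites, dem)
  expect_equal(out$elevation_q25, 1.75)

  # uniform field -> that value; point site -> containing cell
  dem2 <- grid_raster(matrix(2, 3, 3), cell = 1)
  out2 <- site_elevation(dplyr::mutate(sites,
    footprint = list(floodequity:::as_footprint(square(0, 0, 3)))), dem2)
  expect_equal(out2$elevation_q25, 2)
  pt <- dplyr::mutate(sites, footprint = list(floodequity:::point_footprint(0.5, 1.5)))
  expect_equal(site_elevation(pt, dem)$elevation_q25, 3)
})

test_that("full ingest yields a clean category partition on synthetic data", {
  r <- small_region()
  s <- ingest_sites(r$raw_sites, r$parcels, r$land, r$blockgroups, r$dem,
                    r$gauges)
  expect_false(any(duplicated(s$site_id)))
  expect_true(all(s$category %in% floodequity:::SITE_CATEGORIES))
  expect_true(all(is.finite(s$elevation_q25)))
  expect_true(all(s$gauge_id %in% r$gauges$gauge_id))
  # non-point footprints are non-empty and on land
  for (i in seq_len(nrow(s))) {
    fp <- s$footprint[[i]]
    if (!floodequity:::fp_is_point(fp)) {
      expect_gt(floodequity:::fp_area(fp), 0)
    }
  }
  # offshore wells from the generator never survive
  expect_true(all(s$x[s$category == "oil_gas_well"] >= 0))
})
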