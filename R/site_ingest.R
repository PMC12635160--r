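# Cleaning raw hazardous-site records into analysis-ready sites:
# filtering, categorization, fuzzy-address deduplication, footprint
# assignment (parcel join with median-area buffer fallback), FUDS overlap
# resolution, coastline clipping, offshore-well exclusion and site-elevation
# extraction.

## ---- exclusion logging ---------------------------------------------------

append_exclusions <- function(x, prior, stage, rule, n) {
  log <- dplyr::bind_rows(prior,
                          tibble::tibble(stage = stage, rule = rule,
                                         n = as.integer(n)))
  attr(x, "exclusions") <- log
  x
}

#' Exclusion log of a cleaning step
#'
#' Each cleaning function records how many records every rule removed.
#' @param x output of a cleaning step
#' @return tibble with columns stage, rule, n
#' @export
exclusion_log <- function(x) {
  lg <- attr(x, "exclusions")
  if (is.null(lg)) tibble::tibble(stage = character(), rule = character(),
                                  n = integer()) else lg
}

## ---- filtering -----------------------------------------------------------

#' Filter raw site records on locational accuracy and closure status
#'
#' Drops records with locational inaccuracy above `max_accuracy_m` (or
#' zip-code-level provenance, when a logical `zip_level` column is present)
#' and records closed or remediated on or before `closure_year`. Inactive
#' facilities and facilities with expired permits are retained, since
#' residual hazardous material may remain on site.
#'
#' @param records raw site records tibble (columns `accuracy_m`, `end_date`;
#'   optional `zip_level`, `remediated`)
#' @param max_accuracy_m accuracy cutoff in meters (default 50)
#' @param closure_year records with `end_date` at or before this year drop
#' @return filtered tibble with an [exclusion_log()]
#' @export
filter_records <- function(records, max_accuracy_m = 50, closure_year = 2020) {
  imprecise <- !is.na(records$accuracy_m) & records$accuracy_m > max_accuracy_m
  if ("zip_level" %in% names(records)) {
    imprecise <- imprecise | (!is.na(records$zip_level) & records$zip_level)
  }
  closed <- !is.na(records$end_date) & records$end_date <= closure_year
  if ("remediated" %in% names(records)) {
    closed <- closed | (!is.na(records$remediated) & records$remediated)
  }
  out <- records[!imprecise & !closed, , drop = FALSE]
  out <- append_exclusions(out, NULL, "filter",
                           sprintf("accuracy > %g m or zip-level", max_accuracy_m),
                           sum(imprecise))
  append_exclusions(out, exclusion_log(out), "filter",
                    sprintf("closed/remediated by %d", closure_year),
                    sum(closed & !imprecise))
}

## ---- categorization ------------------------------------------------------

#' Default categorization rulebook
#'
#' Maps record hints (program codes, NAICS industry codes, keywords) to the
#' eleven analysis categories with a priority order; the generic discharge
#' permit rule maps to `tri_industrial` at low priority, so a specific
#' industry code wins over it.
#'
#' @return tibble with columns category, field, pattern, priority
#' @export
default_rulebook <- function() {
  specific <- CATEGORY_HINTS
  rules <- dplyr::bind_rows(
    tibble::tibble(category = specific$category, field = "program",
                   pattern = specific$program,
                   priority = seq_len(nrow(specific))),
    tibble::tibble(category = specific$category[!is.na(specific$naics)],
                   field = "naics",
                   pattern = specific$naics[!is.na(specific$naics)],
                   priority = 20L + seq_len(sum(!is.na(specific$naics)))),
    tibble::tibble(category = specific$category, field = "keyword",
                   pattern = specific$keyword,
                   priority = 40L + seq_len(nrow(specific))),
    tibble::tibble(category = "tri_industrial", field = "program",
                   pattern = "NPDES", priority = 90L)
  )
  rules[!is.na(rules$pattern), ]
}

#' Assign exactly one category per record
#'
#' Rules are evaluated against the record's hint fields; among matching
#' rules the lowest priority number wins. Records matching no rule are
#' excluded with a logged count; two distinct rules matching one record at
#' equal priority is a rulebook configuration error.
#'
#' @param records filtered records (columns `program`, `naics`, `keyword`)
#' @param rulebook tibble as returned by [default_rulebook()]
#' @return records with a `category` column and an [exclusion_log()]
#' @export
categorize <- function(records, rulebook = default_rulebook()) {
  n <- nrow(records)
  match_rule <- function(field, pattern) {
    v <- records[[field]]
    if (is.null(v)) return(rep(FALSE, n))
    hit <- switch(field,
                  program = !is.na(v) & v == pattern,
                  naics = !is.na(v) & startsWith(v, pattern),
                  keyword = !is.na(v) & grepl(pattern, v, fixed = TRUE),
                  rep(FALSE, n))
    hit
  }
  hits <- vapply(seq_len(nrow(rulebook)),
                 function(k) match_rule(rulebook$field[k], rulebook$pattern[k]),
                 logical(n))
  if (n == 1) hits <- matrix(hits, nrow = 1)
  category <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    k <- which(hits[i, ])
    if (length(k) == 0) next
    pr <- rulebook$priority[k]
    best <- k[pr == min(pr)]
    if (length(best) > 1) {
      stop(sprintf(
        "rulebook configuration error: record %s matches %d rules at equal priority %d",
        records$record_id[i], length(best), min(pr)))
    }
    category[i] <- rulebook$category[best]
  }
  out <- records
  out$category <- category
  dropped <- sum(is.na(category))
  out <- out[!is.na(category), , drop = FALSE]
  append_exclusions(out, exclusion_log(records), "categorize",
                    "no matching rule", dropped)
}

## ---- deduplication -------------------------------------------------------

normalize_address <- function(a) {
  a <- toupper(a)
  a <- gsub("[[:punct:]]", " ", a)
  gsub("\\s+", " ", trimws(a))
}

#' Fuzzy address similarity
#'
#' Normalized indel similarity (1 minus insert/delete edit distance over the
#' summed string lengths) on upper-cased, punctuation-stripped,
#' whitespace-collapsed addresses.
#'
#' @param a,b character vectors (recycled)
#' @return similarity in \[0, 1\]
#' @export
address_similarity <- function(a, b) {
  a <- normalize_address(a); b <- normalize_address(b)
  d <- diag(utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2)))
  tot <- nchar(a) + nchar(b)
  ifelse(tot == 0, 1, 1 - d / tot)
}

#' Collapse duplicate site records
#'
#' Records with the same category, identical coordinates and address
#' similarity at or above the threshold collapse to one record. Identical
#' coordinates with similar addresses in different categories are retained
#' as distinct sites. Identical coordinates with dissimilar addresses are
#' flagged for plausibility review and dropped when the `implausible`
#' predicate (given the flagged group) returns `TRUE`; the default predicate
#' drops them.
#'
#' @param records categorized records
#' @param similarity_threshold fuzzy-match threshold (default 0.8)
#' @param implausible function(tibble of a flagged group) -> logical
#' @return deduplicated tibble with an [exclusion_log()]; flagged groups in
#'   `attr(, "flagged")`
#' @export
dedupe <- function(records, similarity_threshold = 0.8,
                   implausible = function(group) TRUE) {
  key <- paste(records$category, records$x, records$y, sep = "\r")
  keep <- rep(TRUE, nrow(records))
  flagged <- list()
  n_collapsed <- 0L; n_dropped <- 0L
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    m <- length(idx)
    # single-linkage clustering on address similarity
    cluster <- seq_len(m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (address_similarity(records$address[idx[i]],
                             records$address[idx[j]]) >= similarity_threshold) {
        cluster[cluster == cluster[j]] <- cluster[i]
      }
    }
    if (length(unique(cluster)) == 1L) {
      keep[idx[-1]] <- FALSE
      n_collapsed <- n_collapsed + m - 1L
    } else {
      grp <- records[idx, , drop = FALSE]
      flagged[[length(flagged) + 1L]] <- grp
      if (isTRUE(implausible(grp))) {
        keep[idx] <- FALSE
        n_dropped <- n_dropped + m
      } else {
        # plausible co-located distinct facilities: keep one per cluster
        first_of <- !duplicated(cluster)
        keep[idx[!first_of]] <- FALSE
        n_collapsed <- n_collapsed + sum(!first_of)
      }
    }
  }
  out <- records[keep, , drop = FALSE]
  out <- append_exclusions(out, exclusion_log(records), "dedupe",
                           "duplicate collapsed", n_collapsed)
  out <- append_exclusions(out, exclusion_log(out), "dedupe",
                           "implausible co-located records dropped", n_dropped)
  attr(out, "flagged") <- if (length(flagged)) dplyr::bind_rows(flagged) else NULL
  out
}

## ---- footprints ----------------------------------------------------------

point_footprint <- function(x, y) {
  structure(list(matrix(c(x, y), ncol = 2)), class = "footprint",
            point = TRUE)
}

fp_is_point <- function(fp) isTRUE(attr(fp, "point"))

#' Assign footprints from tax parcels or median-area buffers
#'
#' Non-well, non-FUDS records whose coordinates fall inside a tax parcel
#' take that parcel as footprint; the rest get a circular buffer whose area
#' equals the category's median intersected-parcel area. Wells keep point
#' geometry.
#'
#' @param records categorized, deduplicated records
#' @param parcels parcels tibble (`parcel_id`, `geometry`)
#' @param category_median_areas optional named fallback areas (m^2) for
#'   categories where no record intersects a parcel
#' @return site-draft tibble: site_id, category, footprint (list-column),
#'   provenance, x, y
#' @export
assign_footprint <- function(records, parcels, category_median_areas = NULL) {
  stopifnot(!any(records$category == "fuds"))
  n <- nrow(records)
  fp <- vector("list", n)
  prov <- character(n)
  hit_area <- rep(NA_real_, n)

  pts <- cbind(records$x, records$y)
  parcel_idx <- rep(NA_integer_, n)
  nonwell <- records$category != "oil_gas_well"
  for (j in seq_len(nrow(parcels))) {
    g <- parcels$geometry[[j]]
    cand <- which(nonwell & is.na(parcel_idx) &
                    pts[, 1] >= min(g[, 1]) & pts[, 1] <= max(g[, 1]) &
                    pts[, 2] >= min(g[, 2]) & pts[, 2] <= max(g[, 2]))
    if (length(cand) == 0) next
    inside <- sp::point.in.polygon(pts[cand, 1], pts[cand, 2],
                                   g[, 1], g[, 2]) > 0
    parcel_idx[cand[inside]] <- j
  }
  hit <- !is.na(parcel_idx)
  for (i in which(hit)) {
    fp[[i]] <- as_footprint(parcels$geometry[[parcel_idx[i]]])
    prov[i] <- "parcel"
    hit_area[i] <- poly_area(parcels$geometry[[parcel_idx[i]]])
  }
  med_area <- tapply(hit_area[nonwell], records$category[nonwell],
                     stats::median, na.rm = TRUE)
  for (i in which(nonwell & !hit)) {
    cat_i <- records$category[i]
    a_med <- med_area[[cat_i]]
    if (is.null(a_med) || is.na(a_med)) a_med <- category_median_areas[[cat_i]]
    if (is.null(a_med) || is.na(a_med)) {
      stop(sprintf(
        "category '%s' has no parcel-intersecting records and no fallback median area",
        cat_i))
    }
    fp[[i]] <- as_footprint(circle_polygon(pts[i, ], sqrt(a_med / pi)))
    prov[i] <- "buffer"
  }
  for (i in which(!nonwell)) {
    fp[[i]] <- point_footprint(pts[i, 1], pts[i, 2])
    prov[i] <- "point"
  }
  out <- tibble::tibble(site_id = records$record_id,
                        category = records$category,
                        footprint = fp, provenance = prov,
                        x = records$x, y = records$y)
  attr(out, "exclusions") <- exclusion_log(records)
  out
}

## ---- FUDS overlap resolution ---------------------------------------------

#' Resolve overlapping FUDS geometries into non-overlapping sites
#'
#' All polygons are included; points inside a polygon are duplicates of it
#' and dropped; points outside every polygon get a circular buffer whose
#' area equals the median polygon area. A buffered point overlapping a
#' polygon is clipped by the polygon. For overlapping polygon pairs the
#' overlap ratio (overlap area over the smaller polygon's area) decides:
#' at or below 0.45 the overlap is split evenly along the perpendicular
#' bisector of the two centroids; above 0.45 the two are merged into one
#' site (convex hull). Connected components of three or more mutually
#' overlapping polygons are emitted unresolved with a flag and excluded
#' from the resolved output.
#'
#' @param fuds_records records with category "fuds"; `geometry` list-column
#'   holds a polygon matrix or `NULL` for point records
#' @param split_ratio merge/split boundary on the overlap ratio
#' @return site-draft tibble (resolved, pairwise-disjoint footprints);
#'   unresolved components in `attr(, "unresolved")`
#' @export
resolve_fuds <- function(fuds_records, split_ratio = 0.45) {
  is_poly <- !vapply(fuds_records$geometry, is.null, logical(1))
  polys <- fuds_records[is_poly, , drop = FALSE]
  pnts <- fuds_records[!is_poly, , drop = FALSE]
  n_drop_inside <- 0L

  items <- purrr::map(polys$geometry, as_footprint)
  ids <- polys$record_id
  prov <- rep("fuds_polygon", length(items))

  if (nrow(pnts) > 0) {
    med_area <- stats::median(vapply(items, fp_area, numeric(1)))
    for (i in seq_len(nrow(pnts))) {
      p <- c(pnts$x[i], pnts$y[i])
      inside <- any(vapply(items[prov == "fuds_polygon"],
                           function(f) fp_contains(f, p), logical(1)))
      if (inside) { n_drop_inside <- n_drop_inside + 1L; next }
      items[[length(items) + 1L]] <- as_footprint(
        circle_polygon(p, sqrt(med_area / pi)))
      ids <- c(ids, pnts$record_id[i])
      prov <- c(prov, "fuds_buffer")
    }
  }

  unresolved <- tibble::tibble(record_id = character(),
                               component = integer())
  comp_counter <- 0L

  for (pass in 1:6) {
    m <- length(items)
    if (m <= 1) break
    # buffered points are clipped by every polygon they touch before pair
    # resolution, so mixed components cannot arise
    drop <- logical(m)
    for (b in which(prov == "fuds_buffer")) {
      for (p in which(prov != "fuds_buffer")) {
        if (bbox_gap(fp_bbox(items[[b]]), fp_bbox(items[[p]])) > 0) next
        if (fp_intersection_area(items[[b]], items[[p]]) <= AREA_EPS) next
        for (q in unclass(items[[p]])) items[[b]] <- fp_diff(items[[b]], q)
        if (fp_is_empty(items[[b]])) { drop[b] <- TRUE; break }
      }
    }
    items <- items[!drop]; ids <- ids[!drop]; prov <- prov[!drop]
    m <- length(items)
    if (m <= 1) break

    ov <- matrix(FALSE, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (bbox_gap(fp_bbox(items[[i]]), fp_bbox(items[[j]])) > 0) next
      ov[i, j] <- ov[j, i] <- fp_intersection_area(items[[i]], items[[j]]) > AREA_EPS
    }
    if (!any(ov)) break
    comp <- components_from_adjacency(ov)
    drop <- logical(m)
    changed <- FALSE
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) == 1) next
      if (length(members) >= 3) {
        comp_counter <- comp_counter + 1L
        unresolved <- dplyr::bind_rows(unresolved, tibble::tibble(
          record_id = ids[members], component = comp_counter))
        drop[members] <- TRUE
        changed <- TRUE
        next
      }
      i <- members[1]; j <- members[2]
      res <- resolve_polygon_pair(items[[i]], items[[j]], split_ratio)
      if (res$action == "merge") {
        items[[i]] <- res$merged
        ids[i] <- paste(ids[i], ids[j], sep = "+")
        drop[j] <- TRUE
      } else {
        items[[i]] <- res$a
        items[[j]] <- res$b
      }
      changed <- TRUE
    }
    items <- items[!drop]; ids <- ids[!drop]; prov <- prov[!drop]
    if (!changed) break
  }

  ctr <- t(vapply(items, fp_centroid, numeric(2)))
  out <- tibble::tibble(site_id = ids, category = "fuds",
                        footprint = items, provenance = prov,
                        x = if (length(items)) ctr[, 1] else numeric(0),
                        y = if (length(items)) ctr[, 2] else numeric(0))
  out <- append_exclusions(out, exclusion_log(fuds_records), "resolve_fuds",
                           "point duplicate of polygon", n_drop_inside)
  out <- append_exclusions(out, exclusion_log(out), "resolve_fuds",
                           "unresolved >=3-way overlap",
                           length(unique(unresolved$record_id)))
  attr(out, "unresolved") <- if (nrow(unresolved)) unresolved else NULL
  out
}

components_from_adjacency <- function(adj) {
  m <- nrow(adj)
  comp <- rep(NA_integer_, m)
  cid <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Split (ratio <= split_ratio) or merge (ratio > split_ratio) a pair of
# overlapping footprints whose pieces are convex.
resolve_polygon_pair <- function(fa, fb, split_ratio = 0.45) {
  inter_area <- fp_intersection_area(fa, fb)
  ratio <- inter_area / min(fp_area(fa), fp_area(fb))
  if (ratio > split_ratio) {
    verts <- do.call(rbind, c(unclass(fa), unclass(fb)))
    return(list(action = "merge", ratio = ratio,
                merged = as_footprint(convex_hull_poly(verts))))
  }
  # split the overlap along the perpendicular bisector of the centroids
  ca <- fp_centroid(fa); cb <- fp_centroid(fb)
  d <- cb - ca
  mid <- (ca + cb) / 2
  # halfplane containing ca: d . (p - mid) <= 0
  a_new <- fa; b_new <- fb
  for (p in unclass(fb)) for (q in unclass(fa)) {
    o <- poly_clip(q, p)
    if (is.null(o)) next
    a_new <- fp_diff(a_new, o)
    b_new <- fp_diff(b_new, o)
    near_a <- clip_halfplane(o, d[1], d[2], sum(d * mid))
    near_b <- clip_halfplane(o, -d[1], -d[2], -sum(d * mid))
    if (!is.null(near_a)) a_new <- structure(c(unclass(a_new), list(near_a)),
                                             class = "footprint")
    if (!is.null(near_b)) b_new <- structure(c(unclass(b_new), list(near_b)),
                                             class = "footprint")
  }
  list(action = "split", ratio = ratio, a = a_new, b = b_new)
}

## ---- coastline clipping and offshore exclusion ---------------------------

#' Clip site footprints at the coastline
#'
#' Footprints are intersected with the land polygon; sites left with an
#' empty footprint are dropped with a logged count. Point sites are kept
#' only when on land (boundary inclusive).
#'
#' @param sites site-draft tibble
#' @param land convex land polygon (vertex matrix)
#' @return clipped tibble with an [exclusion_log()]
#' @export
clip_to_coast <- function(sites, land) {
  n <- nrow(sites)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    fp <- sites$footprint[[i]]
    # point sites have no area to clip; offshore wells are handled by the
    # block-group coverage rule, not the coastline clip
    if (fp_is_point(fp)) next
    clipped <- fp_clip(fp, land)
    if (fp_is_empty(clipped)) keep[i] <- FALSE else sites$footprint[[i]] <- clipped
  }
  out <- sites[keep, , drop = FALSE]
  append_exclusions(out, exclusion_log(sites), "clip_to_coast",
                    "footprint entirely seaward", sum(!keep))
}

#' Exclude offshore oil and gas wells
#'
#' Well points not covered by any block-group polygon (boundary inclusive)
#' are removed; other categories pass through.
#'
#' @param sites site-draft tibble
#' @param blockgroups block-group tibble with `geometry`
#' @return tibble with offshore wells removed and an [exclusion_log()]
#' @export
exclude_offshore_wells <- function(sites, blockgroups) {
  wells <- which(sites$category == "oil_gas_well")
  if (length(wells) == 0) return(sites)
  onland <- rep(FALSE, length(wells))
  for (g in blockgroups$geometry) {
    todo <- which(!onland)
    if (length(todo) == 0) break
    px <- sites$x[wells[todo]]; py <- sites$y[wells[todo]]
    cand <- px >= min(g[, 1]) & px <= max(g[, 1]) &
      py >= min(g[, 2]) & py <= max(g[, 2])
    if (!any(cand)) next
    inside <- sp::point.in.polygon(px[cand], py[cand], g[, 1], g[, 2]) > 0
    onland[todo[cand][inside]] <- TRUE
  }
  drop <- wells[!onland]
  out <- if (length(drop)) sites[-drop, , drop = FALSE] else sites
  append_exclusions(out, exclusion_log(sites), "exclude_offshore_wells",
                    "well beyond block-group boundaries", length(drop))
}

## ---- site elevation ------------------------------------------------------

#' Footprint elevation summary: 25th percentile
#'
#' Linear-interpolated 25th percentile of DEM values at cell centers inside
#' the footprint. Point sites take the containing cell's value; polygon
#' footprints smaller than a cell fall back to the centroid cell.
#'
#' @param sites site-draft tibble
#' @param dem a [grid_raster()] of elevation (m above MHHW)
#' @param probs percentile (default 0.25)
#' @return sites with an `elevation_q25` column
#' @export
site_elevation <- function(sites, dem, probs = 0.25) {
  n <- nrow(sites)
  z <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fp <- sites$footprint[[i]]
    if (fp_is_point(fp)) {
      z[i] <- raster_value_at(dem, fp[[1]])
    } else {
      cells <- raster_cells_in_fp(dem, fp)
      vals <- cells$values[!is.na(cells$values)]
      if (length(vals) == 0) {
        z[i] <- raster_value_at(dem, matrix(fp_centroid(fp), ncol = 2))
      } else {
        z[i] <- unname(stats::quantile(vals, probs = probs, type = 7))
      }
    }
    if (is.na(z[i])) {
      stop(sprintf("site %s: footprint covers no DEM cell with data",
                   sites$site_id[i]))
    }
  }
  sites$elevation_q25 <- z
  sites
}

## ---- full ingest pipeline ------------------------------------------------

#' Clean raw records into analysis-ready hazardous sites
#'
#' Runs filtering, categorization, deduplication, footprint assignment
#' (parcels / buffers / FUDS resolution), coastline clipping, offshore-well
#' exclusion, site-elevation extraction and nearest-gauge assignment.
#'
#' @param raw raw site records tibble
#' @param parcels parcels tibble
#' @param land convex land polygon
#' @param blockgroups block-group tibble
#' @param dem elevation [grid_raster()]
#' @param gauges gauges tibble (gauge_id, x, y)
#' @param rulebook categorization rulebook
#' @param similarity_threshold dedupe threshold
#' @return HazardSite tibble: site_id, category, footprint, provenance,
#'   elevation_q25, gauge_id; cumulative [exclusion_log()]
#' @export
ingest_sites <- function(raw, parcels, land, blockgroups, dem, gauges,
                         rulebook = default_rulebook(),
                         similarity_threshold = 0.8) {
  step <- filter_records(raw)
  step <- categorize(step, rulebook)
  step <- dedupe(step, similarity_threshold)

  fuds <- step[step$category == "fuds", , drop = FALSE]
  rest <- step[step$category != "fuds", , drop = FALSE]
  drafts <- assign_footprint(rest, parcels)
  log_so_far <- exclusion_log(drafts)
  if (nrow(fuds) > 0) {
    attr(fuds, "exclusions") <- NULL  # avoid double-counting the shared log
    fdrafts <- resolve_fuds(fuds)
    log_so_far <- dplyr::bind_rows(log_so_far, exclusion_log(fdrafts))
    drafts <- dplyr::bind_rows(drafts, fdrafts)
  }
  attr(drafts, "exclusions") <- log_so_far

  drafts <- clip_to_coast(drafts, land)
  drafts <- exclude_offshore_wells(drafts, blockgroups)
  drafts <- site_elevation(drafts, dem)

  gx <- gauges$x; gy <- gauges$y
  ctr <- t(vapply(drafts$footprint, fp_centroid, numeric(2)))
  nearest <- vapply(seq_len(nrow(drafts)), function(i) {
    which.min((gx - ctr[i, 1])^2 + (gy - ctr[i, 2])^2)
  }, integer(1))
  drafts$gauge_id <- gauges$gauge_id[nearest]
  drafts
}
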