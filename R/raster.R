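# Minimal single-band grid raster on the local planar CRS.
#
# values is a numeric matrix with rows running south -> north (row 1 is the
# southernmost row) and columns west -> east, so values[r, c] sits at
# x = xmin + (c - 0.5) * cell, y = ymin + (r - 0.5) * cell.

#' Construct a grid raster
#'
#' @param values numeric matrix, row 1 = southernmost row
#' @param xmin,ymin coordinates of the lower-left raster corner (m)
#' @param cell cell size (m)
#' @param nodata nodata sentinel used on write
#' @return a `grid_raster` object
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cell = 30, nodata = -9999) {
  stopifnot(is.matrix(values), cell > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cell = cell, nodata = nodata),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells, %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell, x$xmin, x$ymin))
  invisible(x)
}

raster_dim <- function(r) dim(r$values)

# Cell-center coordinates of every cell, in column-major order matching
# as.vector(r$values).
raster_centers <- function(r) {
  d <- dim(r$values)
  cx <- r$xmin + (seq_len(d[2]) - 0.5) * r$cell
  cy <- r$ymin + (seq_len(d[1]) - 0.5) * r$cell
  cbind(x = rep(cx, each = d[1]), y = rep(cy, times = d[2]))
}

# Value of the cell containing each point; NA outside the raster.
raster_value_at <- function(r, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  d <- dim(r$values)
  col <- floor((pts[, 1] - r$xmin) / r$cell) + 1L
  row <- floor((pts[, 2] - r$ymin) / r$cell) + 1L
  ok <- col >= 1L & col <= d[2] & row >= 1L & row <= d[1]
  out <- rep(NA_real_, nrow(pts))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

# Indices + centers + values of cells whose centers fall inside a footprint,
# prefiltered by the footprint bounding box.
raster_cells_in_fp <- function(r, fp) {
  bb <- fp_bbox(fp)
  d <- dim(r$values)
  c0 <- max(1L, floor((bb["xmin"] - r$xmin) / r$cell) + 1L)
  c1 <- min(d[2], ceiling((bb["xmax"] - r$xmin) / r$cell))
  r0 <- max(1L, floor((bb["ymin"] - r$ymin) / r$cell) + 1L)
  r1 <- min(d[1], ceiling((bb["ymax"] - r$ymin) / r$cell))
  if (c0 > c1 || r0 > r1) {
    return(list(centers = matrix(numeric(0), ncol = 2), values = numeric(0)))
  }
  cols <- c0:c1; rows <- r0:r1
  cx <- r$xmin + (cols - 0.5) * r$cell
  cy <- r$ymin + (rows - 0.5) * r$cell
  pts <- cbind(rep(cx, each = length(rows)), rep(cy, times = length(cols)))
  keep <- fp_contains(fp, pts)
  vals <- as.vector(r$values[rows, cols, drop = FALSE])[keep]
  list(centers = pts[keep, , drop = FALSE], values = vals)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS tools; the
#' local planar CRS (meters) is recorded by the fixture-bundle manifest.
#' @param r a `grid_raster`
#' @param path output path (conventionally `.asc`)
#' @export
write_ascii_grid <- function(r, path) {
  d <- dim(r$values)
  v <- r$values
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cell),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  # ASC rows run north -> south
  for (i in rev(seq_len(d[1]))) {
    writeLines(paste(format(v[i, ], digits = 10, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path path to a `.asc` file
#' @return a `grid_raster`
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- as.integer(val("ncols")); nrows <- as.integer(val("nrows"))
  nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  v <- matrix(scan(text = paste(body, collapse = "\n"), quiet = TRUE),
              nrow = nrows, ncol = ncols, byrow = TRUE)
  v <- v[rev(seq_len(nrows)), , drop = FALSE]  # back to south-first rows
  v[v == nodata] <- NA_real_
  grid_raster(v, xmin = val("xllcorner"), ymin = val("yllcorner"),
              cell = val("cellsize"), nodata = nodata)
}
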