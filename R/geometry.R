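# Planar geometry primitives on a local metric CRS.
#
# All analysis geometry lives on a synthetic planar coordinate system in
# meters, so Euclidean math is exact. Polygons are two-column (x, y) numeric
# matrices with vertices in counter-clockwise order, not closed. Site
# footprints are "footprint" objects: lists of disjoint convex pieces, which
# keeps clipping, subtraction and area bookkeeping exact without a full
# computational-geometry dependency.

AREA_EPS <- 1e-6  # m^2; pieces below this are numerical slivers

#' Signed and absolute polygon area
#' @param p two-column vertex matrix
#' @return area in square meters
#' @keywords internal
poly_area <- function(p) abs(poly_area_signed(p))

poly_area_signed <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

poly_centroid <- function(p) {
  n <- nrow(p)
  if (n < 3) return(c(mean(p[, 1]), mean(p[, 2])))
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

ensure_ccw <- function(p) {
  if (poly_area_signed(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

#' Regular-polygon approximation of a circle
#'
#' Used for buffer footprints; 64 vertices keeps the area within 0.2% of the
#' true circle.
#' @param center length-2 numeric (x, y) in meters
#' @param radius radius in meters
#' @param n number of vertices
#' @return vertex matrix (counter-clockwise)
#' @export
circle_polygon <- function(center, radius, n = 64L) {
  stopifnot(radius > 0, n >= 8)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

rect_polygon <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# Clip polygon to the halfplane a*x + b*y <= c (Sutherland-Hodgman, one edge).
clip_halfplane <- function(p, a, b, c) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(NULL)
  f <- a * p[, 1] + b * p[, 2] - c
  if (all(f <= 0)) return(p)
  if (all(f >= 0)) return(NULL)
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    fi <- f[i]; fj <- f[j]
    if (fi <= 0) { out_x <- c(out_x, p[i, 1]); out_y <- c(out_y, p[i, 2]) }
    if ((fi < 0 && fj > 0) || (fi > 0 && fj < 0)) {
      t <- fi / (fi - fj)
      out_x <- c(out_x, p[i, 1] + t * (p[j, 1] - p[i, 1]))
      out_y <- c(out_y, p[i, 2] + t * (p[j, 2] - p[i, 2]))
    }
  }
  if (length(out_x) < 3) return(NULL)
  q <- cbind(out_x, out_y)
  dimnames(q) <- NULL
  if (poly_area(q) < AREA_EPS) NULL else q
}

# Edge (p1 -> p2) of a ccw polygon: interior is to the left, i.e.
# dy*x - dx*y <= dy*x1 - dx*y1.
edge_halfplanes <- function(q) {
  q <- ensure_ccw(q)
  n <- nrow(q)
  j <- c(2:n, 1)
  dx <- q[j, 1] - q[, 1]
  dy <- q[j, 2] - q[, 2]
  cbind(a = dy, b = -dx, c = dy * q[, 1] - dx * q[, 2])
}

# Intersection of polygon p with convex polygon q.
poly_clip <- function(p, q) {
  hp <- edge_halfplanes(q)
  out <- p
  for (k in seq_len(nrow(hp))) {
    out <- clip_halfplane(out, hp[k, 1], hp[k, 2], hp[k, 3])
    if (is.null(out)) return(NULL)
  }
  out
}

# Convex difference p \ q as a list of disjoint convex pieces ("fan" method):
# for edge i of q the piece outside edge i but inside edges 1..i-1.
poly_diff_convex <- function(p, q) {
  hp <- edge_halfplanes(q)
  pieces <- list()
  remaining <- p
  for (k in seq_len(nrow(hp))) {
    outside <- clip_halfplane(remaining, -hp[k, 1], -hp[k, 2], -hp[k, 3])
    if (!is.null(outside)) pieces[[length(pieces) + 1L]] <- outside
    remaining <- clip_halfplane(remaining, hp[k, 1], hp[k, 2], hp[k, 3])
    if (is.null(remaining)) break
  }
  pieces
}

convex_hull_poly <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  ensure_ccw(pts[idx, , drop = FALSE])
}

## ---- footprints: lists of disjoint convex pieces -------------------------

footprint <- function(...) {
  fp <- list(...)
  fp <- fp[!vapply(fp, is.null, logical(1))]
  structure(fp, class = "footprint")
}

as_footprint <- function(x) {
  if (inherits(x, "footprint")) return(x)
  if (is.matrix(x)) return(footprint(ensure_ccw(x)))
  if (is.list(x)) return(structure(lapply(x, ensure_ccw), class = "footprint"))
  stop("cannot coerce to footprint")
}

fp_area <- function(fp) sum(vapply(fp, poly_area, numeric(1)))

fp_is_empty <- function(fp) length(fp) == 0L

fp_bbox <- function(fp) {
  xs <- unlist(lapply(fp, function(p) range(p[, 1])))
  ys <- unlist(lapply(fp, function(p) range(p[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

fp_centroid <- function(fp) {
  a <- vapply(fp, poly_area, numeric(1))
  cs <- vapply(fp, poly_centroid, numeric(2))
  if (sum(a) == 0) return(rowMeans(cs))
  as.numeric(cs %*% a / sum(a))
}

# Intersect a footprint with a convex polygon.
fp_clip <- function(fp, q) {
  out <- lapply(fp, poly_clip, q = q)
  structure(out[!vapply(out, is.null, logical(1))], class = "footprint")
}

# Subtract a convex polygon from a footprint.
fp_diff <- function(fp, q) {
  out <- unlist(lapply(fp, poly_diff_convex, q = q), recursive = FALSE)
  structure(out, class = "footprint")
}

# Intersection area of two footprints.
fp_intersection_area <- function(fp1, fp2) {
  tot <- 0
  for (p in fp1) for (q in fp2) {
    r <- poly_clip(p, q)
    if (!is.null(r)) tot <- tot + poly_area(r)
  }
  tot
}

# Point-in-footprint test; boundary counts as inside.
fp_contains <- function(fp, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  inside <- rep(FALSE, nrow(pts))
  for (p in fp) {
    if (all(inside)) break
    hit <- sp::point.in.polygon(pts[, 1], pts[, 2], p[, 1], p[, 2]) > 0
    inside <- inside | hit
  }
  inside
}

## ---- distances -----------------------------------------------------------

# Distances from points to the segments of one polygon's boundary (min over
# edges), vectorized over points.
dist_points_segments <- function(pts, p) {
  n <- nrow(p)
  if (n == 1L) {
    return(sqrt((pts[, 1] - p[1, 1])^2 + (pts[, 2] - p[1, 2])^2))
  }
  j <- c(2:n, 1)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    ax <- p[i, 1]; ay <- p[i, 2]
    dx <- p[j[i], 1] - ax; dy <- p[j[i], 2] - ay
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      d <- sqrt((pts[, 1] - ax)^2 + (pts[, 2] - ay)^2)
    } else {
      t <- pmin(1, pmax(0, ((pts[, 1] - ax) * dx + (pts[, 2] - ay) * dy) / L2))
      d <- sqrt((pts[, 1] - (ax + t * dx))^2 + (pts[, 2] - (ay + t * dy))^2)
    }
    best <- pmin(best, d)
  }
  best
}

# Euclidean distance from points to a footprint (0 for points inside).
dist_points_fp <- function(pts, fp) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  d <- rep(Inf, nrow(pts))
  for (p in fp) d <- pmin(d, dist_points_segments(pts, p))
  d[fp_contains(fp, pts)] <- 0
  d
}

# Distance between two footprints (0 if they touch or overlap). Exact for
# convex pieces: realized at a vertex of one piece and an edge of the other.
dist_fp_fp <- function(fp1, fp2) {
  best <- Inf
  for (p in fp1) for (q in fp2) {
    # overlap checks: area intersection, or vertex containment (covers
    # degenerate point "polygons" with fewer than 3 vertices)
    if (nrow(p) >= 3 && nrow(q) >= 3 && !is.null(poly_clip(p, q))) return(0)
    if (nrow(q) >= 3 && any(sp::point.in.polygon(p[, 1], p[, 2],
                                                 q[, 1], q[, 2]) > 0)) return(0)
    if (nrow(p) >= 3 && any(sp::point.in.polygon(q[, 1], q[, 2],
                                                 p[, 1], p[, 2]) > 0)) return(0)
    dpq <- if (nrow(q) >= 2) min(dist_points_segments(p, q)) else
      min(sqrt((p[, 1] - q[1, 1])^2 + (p[, 2] - q[1, 2])^2))
    dqp <- if (nrow(p) >= 2) min(dist_points_segments(q, p)) else dpq
    best <- min(best, dpq, dqp)
  }
  best
}

# Lower bound on footprint-footprint distance from bounding boxes.
bbox_gap <- function(b1, b2) {
  dx <- pmax(0, pmax(b1["xmin"] - b2["xmax"], b2["xmin"] - b1["xmax"]))
  dy <- pmax(0, pmax(b1["ymin"] - b2["ymax"], b2["ymin"] - b1["ymax"]))
  unname(sqrt(dx^2 + dy^2))
}
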