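# Plane-geometry helpers for contour shape analysis.
# Coordinates are 0-based pixel centers, top-left origin, y downward.
# Bounding boxes are half-open [x0, x1) x [y0, y1) in pixels.

# Signed area of a closed polygon (shoelace); positive for one winding,
# negative for the other. `pts` is an n x 2 matrix.
polygon_area_signed <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1L]; y <- pts[, 2L]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_perimeter <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  d <- pts - pts[c(n, seq_len(n - 1L)), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# Perpendicular distance of points to the segment a-b.
point_segment_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(pts, 2L, a)^2)))
  t <- pmin(1, pmax(0, (sweep(pts, 2L, a) %*% ab) / len2))
  proj <- cbind(a[1L] + t * ab[1L], a[2L] + t * ab[2L])
  sqrt(rowSums((pts - proj)^2))
}

# Ramer-Douglas-Peucker on an open chain of points (keeps endpoints).
rdp_chain <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  d <- point_segment_dist(pts[2:(n - 1L), , drop = FALSE], pts[1L, ], pts[n, ])
  i <- which.max(d)
  if (d[i] <= eps) {
    pts[c(1L, n), , drop = FALSE]
  } else {
    k <- i + 1L
    left <- rdp_chain(pts[1:k, , drop = FALSE], eps)
    right <- rdp_chain(pts[k:n, , drop = FALSE], eps)
    rbind(left, right[-1L, , drop = FALSE])
  }
}

# Closed-contour polygon simplification. Splits the ring at the two
# mutually farthest points (two-sweep heuristic), simplifies each half,
# and rejoins. Returns an m x 2 matrix of vertices (no repeated endpoint).
simplify_contour <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 3L) return(pts)
  d0 <- sqrt(rowSums(sweep(pts, 2L, pts[1L, ])^2))
  i <- which.max(d0)
  d1 <- sqrt(rowSums(sweep(pts, 2L, pts[i, ])^2))
  j <- which.max(d1)
  lo <- min(i, j); hi <- max(i, j)
  half1 <- pts[lo:hi, , drop = FALSE]
  half2 <- pts[c(hi:n, 1:lo), , drop = FALSE]
  s1 <- rdp_chain(half1, eps)
  s2 <- rdp_chain(half2, eps)
  out <- rbind(s1, s2[-1L, , drop = FALSE])
  out <- out[-nrow(out), , drop = FALSE]  # ring: last point == first
  unique_rows(out)
}

unique_rows <- function(m) m[!duplicated(m), , drop = FALSE]

# TRUE iff the polygon (vertices in order, no repeated endpoint) is convex:
# all non-zero cross products of consecutive edges share a sign.
is_convex_polygon <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  e <- pts[nxt, , drop = FALSE] - pts
  cr <- e[, 1L] * e[nxt, 2L] - e[, 2L] * e[nxt, 1L]
  cr <- cr[abs(cr) > sqrt(.Machine$double.eps)]
  if (length(cr) == 0L) return(FALSE)  # degenerate / collinear
  all(cr > 0) || all(cr < 0)
}

# Intersection-over-smaller-area of two half-open bboxes c(x0, y0, x1, y1).
bbox_overlap_frac <- function(a, b) {
  ix <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  iy <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- ix * iy
  smaller <- min((a[3L] - a[1L]) * (a[4L] - a[2L]),
                 (b[3L] - b[1L]) * (b[4L] - b[2L]))
  if (smaller <= 0) return(0)
  inter / smaller
}
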