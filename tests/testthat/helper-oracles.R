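# Independent oracles used to cross-check the package's geometry and
# statistics. Deliberately written with different algorithms than the
# implementation: triangle-fan area instead of the shoelace sum, an O(n^3)
# all-pairs hull, cross-product segment intersection instead of
# Liang-Barsky clipping, and explicit sums of squares for the ANOVA F.

# polygon area (km2) by fan triangulation from the first vertex
oracle_area_km2 <- function(poly) {
  p <- as.matrix(poly)
  if (isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE)))
    p <- p[-nrow(p), , drop = FALSE]
  a <- 0
  for (i in 2:(nrow(p) - 1)) {
    v1 <- p[i, ] - p[1, ]; v2 <- p[i + 1, ] - p[1, ]
    a <- a + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  abs(a) / 1e6
}

# O(n^3) convex hull: a directed pair (i, j) is a hull edge iff every other
# point lies strictly to its left; hull vertices = endpoints of such edges
oracle_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    others <- setdiff(1:n, c(i, j))
    cross <- (pts[j, 1] - pts[i, 1]) * (pts[others, 2] - pts[i, 2]) -
      (pts[j, 2] - pts[i, 2]) * (pts[others, 1] - pts[i, 1])
    if (all(cross > 0)) on_hull[c(i, j)] <- TRUE
  }
  pts[on_hull, , drop = FALSE]
}

# does segment (a, b) intersect the axis-aligned rectangle [xlo,xhi]x[ylo,yhi]?
# endpoint containment or crossing of any rectangle edge
oracle_seg_rect <- function(a, b, xlo, xhi, ylo, yhi) {
  inside <- function(p) p[1] >= xlo && p[1] <= xhi && p[2] >= ylo && p[2] <= yhi
  if (inside(a) || inside(b)) return(TRUE)
  segseg <- function(p1, p2, p3, p4) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  corners <- list(c(xlo, ylo), c(xhi, ylo), c(xhi, yhi), c(xlo, yhi))
  for (k in 1:4)
    if (segseg(a, b, corners[[k]], corners[[k %% 4 + 1]])) return(TRUE)
  FALSE
}

# exhaustive trips-per-cell count: every (cell, trip, segment) triple
oracle_intensity <- function(fixes_xy, trip_ids, grid) {
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  for (tid in unique(trip_ids)) {
    idx <- which(trip_ids == tid)
    for (r in seq_len(grid$n_rows)) for (cc in seq_len(grid$n_cols)) {
      xlo <- grid$origin_x + (cc - 1) * grid$cell_size; xhi <- xlo + grid$cell_size
      yhi <- grid$origin_y + (grid$n_rows - r + 1) * grid$cell_size
      ylo <- yhi - grid$cell_size
      hit <- FALSE
      for (k in seq_len(length(idx) - 1)) {
        if (oracle_seg_rect(fixes_xy[idx[k], ], fixes_xy[idx[k + 1], ],
                            xlo, xhi, ylo, yhi)) { hit <- TRUE; break }
      }
      if (hit) counts[r, cc] <- counts[r, cc] + 1L
    }
  }
  counts
}

# classical one-way ANOVA F from explicit sums of squares
oracle_anova_F <- function(y, group) {
  group <- as.factor(group)
  gm <- mean(y)
  means <- tapply(y, group, mean)
  ns <- tapply(y, group, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((y - means[group])^2)
  k <- nlevels(group); n <- length(y)
  (ssb / (k - 1)) / (ssw / (n - k))
}
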