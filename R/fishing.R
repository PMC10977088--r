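# Fishing-area and fishing-intensity layers: per-community minimum convex
# polygons over all GPS fixes, a gridded count of distinct trips per cell,
# and percentile-bootstrap confidence intervals on intensity summaries.

#' Minimum convex polygon (MCP) fishing area
#'
#' The classical territory construct: the smallest convex polygon containing
#' every GPS fix of a community's vessels. Requires at least 3 non-collinear
#' points.
#'
#' @param points two-column matrix of planar \code{x}, \code{y} in metres.
#' @param community optional community label.
#' @return Object of class \code{mcp_area}: list with \code{community},
#'   \code{polygon} (hull vertices, counter-clockwise, open ring),
#'   \code{area_km2}, \code{n_fixes}.
#' @examples
#' pts <- cbind(runif(20, 0, 1000), runif(20, 0, 1000))
#' mcp(pts)
#' @export
mcp <- function(points, community = NA_character_) {
  p <- as.matrix(points)
  if (nrow(p) < 3)
    stop("degenerate geometry: MCP needs at least 3 points", call. = FALSE)
  h <- grDevices::chull(p[, 1], p[, 2])
  hull <- p[h, , drop = FALSE]
  if (nrow(hull) < 3 || area_km2(hull) == 0)
    stop("degenerate geometry: all points are collinear", call. = FALSE)
  structure(list(community = community, polygon = hull,
                 area_km2 = area_km2(hull), n_fixes = nrow(p)),
            class = "mcp_area")
}

#' @export
print.mcp_area <- function(x, ...) {
  cat(sprintf("<mcp_area> %s: %.2f km2 from %d fixes (%d hull vertices)\n",
              if (is.na(x$community)) "(unlabelled)" else x$community,
              x$area_km2, x$n_fixes, nrow(x$polygon)))
  invisible(x)
}

#' Per-community MCP fishing areas
#'
#' Computes one MCP per community from projected trip fixes and the summed
#' total fishing area (the study-level figure is the sum of per-community
#' areas, which may overlap).
#'
#' @param fixes fix data.frame with \code{lon}, \code{lat}, \code{community}
#'   columns (rows with \code{NA} trip_id, if present, are ignored).
#' @param crs metric CRS for the hull geometry.
#' @return List with \code{mcps} (list of \code{mcp_area} by community) and
#'   \code{total_km2} (sum of per-community areas).
#' @export
mcp_by_community <- function(fixes, crs = utm_crs(25, TRUE)) {
  f <- fixes
  if ("trip_id" %in% names(f)) f <- f[!is.na(f$trip_id), , drop = FALSE]
  if (!nrow(f)) stop("no fixes to build MCPs from", call. = FALSE)
  sp <- split(f, f$community)
  mcps <- lapply(names(sp), function(cm) {
    xy <- project(cbind(sp[[cm]]$lon, sp[[cm]]$lat), crs)
    mcp(xy, community = cm)
  })
  names(mcps) <- names(sp)
  list(mcps = mcps,
       total_km2 = sum(vapply(mcps, `[[`, numeric(1), "area_km2")))
}

# Cells of `grid` crossed by segment (x0,y0)-(x1,y1): Liang-Barsky clip of
# the segment against each candidate cell rectangle in the segment's bbox.
.segment_cells <- function(grid, x0, y0, x1, y1) {
  cs <- grid$cell_size
  c0 <- floor((min(x0, x1) - grid$origin_x) / cs) + 1
  c1 <- floor((max(x0, x1) - grid$origin_x) / cs) + 1
  r0 <- floor((min(y0, y1) - grid$origin_y) / cs) + 1
  r1 <- floor((max(y0, y1) - grid$origin_y) / cs) + 1
  cols <- max(1, c0):min(grid$n_cols, c1)
  rows_s <- max(1, r0):min(grid$n_rows, r1)
  if (c1 < 1 || c0 > grid$n_cols || r1 < 1 || r0 > grid$n_rows)
    return(matrix(integer(0), 0, 2))
  dx <- x1 - x0; dy <- y1 - y0
  out <- matrix(integer(0), 0, 2)
  for (rs in rows_s) {
    ylo <- grid$origin_y + (rs - 1) * cs; yhi <- ylo + cs
    for (cc in cols) {
      xlo <- grid$origin_x + (cc - 1) * cs; xhi <- xlo + cs
      # Liang-Barsky parameters
      t0 <- 0; t1 <- 1; ok <- TRUE
      for (pq in list(c(-dx, x0 - xlo), c(dx, xhi - x0),
                      c(-dy, y0 - ylo), c(dy, yhi - y0))) {
        p <- pq[1]; q <- pq[2]
        if (p == 0) { if (q < 0) { ok <- FALSE; break } }
        else {
          r <- q / p
          if (p < 0) { if (r > t1) { ok <- FALSE; break }; t0 <- max(t0, r) }
          else { if (r < t0) { ok <- FALSE; break }; t1 <- min(t1, r) }
        }
      }
      if (ok && t0 <= t1)
        out <- rbind(out, c(grid$n_rows - rs + 1L, cc))
    }
  }
  out
}

#' Fishing-intensity grid from trip routes
#'
#' Counts, for every grid cell, the number of distinct fishing trips whose
#' route polyline (consecutive fixes joined by straight segments) crosses the
#' cell. A trip increments a cell at most once, however many times its route
#' re-enters it: intensity is expressed in trips, not fixes or revisits.
#'
#' @param fixes fix data.frame with \code{trip_id}, \code{lon}, \code{lat}
#'   (rows with \code{NA} trip_id ignored).
#' @param grid the analysis \code{\link{grid_spec}}.
#' @return Object of class \code{fishing_intensity}: list with \code{grid},
#'   integer matrix \code{trips_per_cell}, \code{max_trips},
#'   \code{n_trips}.
#' @export
intensity_grid <- function(fixes, grid) {
  f <- fixes[!is.na(fixes$trip_id), , drop = FALSE]
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  if (!nrow(f)) {
    warning("intensity_grid: no trips; returning an all-zero layer",
            call. = FALSE)
    return(structure(list(grid = grid, trips_per_cell = counts,
                          max_trips = 0L, n_trips = 0L),
                     class = "fishing_intensity"))
  }
  xy <- project(cbind(f$lon, f$lat), grid$crs)
  sp <- split(seq_len(nrow(f)), f$trip_id)
  for (idx in sp) {
    hit <- matrix(FALSE, grid$n_rows, grid$n_cols)
    if (length(idx) == 1) {
      rc <- cell_of(grid, xy[idx, 1], xy[idx, 2])
      if (!is.na(rc$row)) hit[rc$row, rc$col] <- TRUE
    } else {
      for (k in seq_len(length(idx) - 1)) {
        cells <- .segment_cells(grid, xy[idx[k], 1], xy[idx[k], 2],
                                xy[idx[k + 1], 1], xy[idx[k + 1], 2])
        if (nrow(cells)) hit[cells] <- TRUE
      }
    }
    counts <- counts + hit
  }
  structure(list(grid = grid, trips_per_cell = counts,
                 max_trips = max(counts), n_trips = length(sp)),
            class = "fishing_intensity")
}

#' @export
print.fishing_intensity <- function(x, ...) {
  cat(sprintf("<fishing_intensity> %d trips; per-cell range 0-%d on %d x %d grid\n",
              x$n_trips, x$max_trips, x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric bootstrap (resampling with replacement, via the boot
#' package) of a configurable summary statistic, with the percentile
#' interval. Deterministic under a fixed seed. The default statistic is the
#' mean; for intensity layers a common choice is the mean of
#' positive-intensity cells.
#'
#' @param values numeric vector (non-empty).
#' @param statistic function of a numeric vector returning one number.
#' @param n_reps bootstrap replications (default 1000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed integer RNG seed.
#' @param statistic_name label stored in the result.
#' @return Object of class \code{bootstrap_ci}: list with \code{statistic},
#'   \code{estimate}, \code{lower}, \code{upper}, \code{level},
#'   \code{n_reps}, \code{seed}, \code{n}.
#' @examples
#' bootstrap_ci(rnorm(50, 5), n_reps = 200, seed = 1)
#' @export
bootstrap_ci <- function(values, statistic = mean, n_reps = 1000,
                         level = 0.95, seed = 1L,
                         statistic_name = "mean") {
  if (!length(values)) stop("bootstrap_ci: empty input", call. = FALSE)
  stopifnot(level > 0, level < 1, n_reps >= 1)
  set.seed(seed)
  b <- boot::boot(values, function(d, i) statistic(d[i]), R = n_reps)
  qs <- stats::quantile(b$t[, 1], c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(statistic = statistic_name, estimate = unname(b$t0),
                 lower = qs[1], upper = qs[2], level = level,
                 n_reps = n_reps, seed = seed, n = length(values)),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %s = %.4f, %g%% CI [%.4f, %.4f] (%d reps, n = %d, seed %d)\n",
              x$statistic, x$estimate, 100 * x$level, x$lower, x$upper,
              x$n_reps, x$n, x$seed))
  invisible(x)
}
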