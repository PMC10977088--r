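# The shared analysis lattice: a regular metric grid of square cells.
# Matrices are stored in raster order (row 1 = northernmost row). Cell
# intervals are half-open, [x, x + cell) x [y, y + cell), so every planar
# point inside the grid extent belongs to exactly one cell.

#' Analysis grid specification
#'
#' A \code{grid_spec} describes the regular square lattice on which habitat,
#' fishing-intensity and risk layers are computed (default cell 1000 m, i.e.
#' 1 km-square cells). The origin is the lower-left corner and is snapped to
#' integer multiples of the cell size, so independently built grids over
#' overlapping extents align cell-for-cell.
#'
#' @param origin_x,origin_y lower-left corner, metres in \code{crs}. Snapped
#'   down to multiples of \code{cell_size}.
#' @param cell_size cell edge length in metres (> 0); default 1000.
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param crs the metric CRS (\code{\link{utm_crs}} or id string).
#' @return An object of class \code{grid_spec}.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size = 1000, n_rows, n_cols,
                      crs = utm_crs(25, TRUE)) {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1)
  crs <- as_crs(crs)
  structure(
    list(
      origin_x = floor(origin_x / cell_size) * cell_size,
      origin_y = floor(origin_y / cell_size) * cell_size,
      cell_size = cell_size,
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      crs = crs
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (%s), origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs$id, x$origin_x, x$origin_y))
  invisible(x)
}

#' Build a grid covering a bounding box
#'
#' Creates the smallest origin-snapped \code{grid_spec} whose union of cells
#' contains \code{bounds} entirely. Bounds may be planar metres or geographic
#' degrees; geographic bounds (all values within +-360) are projected first.
#'
#' @param bounds numeric \code{c(xmin, ymin, xmax, ymax)}; degrees or metres.
#' @inheritParams grid_spec
#' @return A \code{grid_spec}.
#' @examples
#' make_grid(c(-34.9, -7.3, -34.7, -7.1), cell_size = 1000)
#' @export
make_grid <- function(bounds, cell_size = 1000, crs = utm_crs(25, TRUE)) {
  crs <- as_crs(crs)
  stopifnot(length(bounds) == 4, cell_size > 0)
  if (bounds[3] <= bounds[1] || bounds[4] <= bounds[2])
    stop("invalid extent: bounds are degenerate (zero or negative span)",
         call. = FALSE)
  if (all(abs(bounds) <= 360)) {
    corners <- project(cbind(lon = bounds[c(1, 3, 1, 3)],
                             lat = bounds[c(2, 2, 4, 4)]), crs)
    bounds <- c(min(corners[, 1]), min(corners[, 2]),
                max(corners[, 1]), max(corners[, 2]))
  }
  ox <- floor(bounds[1] / cell_size) * cell_size
  oy <- floor(bounds[2] / cell_size) * cell_size
  grid_spec(
    origin_x = ox, origin_y = oy, cell_size = cell_size,
    n_rows = max(1L, ceiling((bounds[4] - oy) / cell_size)),
    n_cols = max(1L, ceiling((bounds[3] - ox) / cell_size)),
    crs = crs
  )
}

grid_xmax <- function(g) g$origin_x + g$n_cols * g$cell_size
grid_ymax <- function(g) g$origin_y + g$n_rows * g$cell_size

grids_aligned <- function(a, b) {
  isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    identical(a$crs$id, b$crs$id)
}

#' Locate planar points on the grid
#'
#' Maps planar coordinates to cell row/column indices under half-open cell
#' intervals (row 1 is the northernmost row). Points outside the grid extent
#' get \code{NA} indices.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param x,y planar coordinates in metres (vectors of equal length).
#' @return \code{cell_of}: data.frame with columns \code{row}, \code{col}.
#' @export
cell_of <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row_s <- floor((y - grid$origin_y) / grid$cell_size) + 1  # from south
  ok <- col >= 1 & col <= grid$n_cols & row_s >= 1 & row_s <= grid$n_rows
  row <- grid$n_rows - row_s + 1L
  row[!ok] <- NA_integer_; col[!ok] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' @rdname cell_of
#' @param row,col cell indices (row 1 = northernmost).
#' @return \code{cell_centroid}: two-column matrix of centroid \code{x},
#'   \code{y} in metres.
#' @export
cell_centroid <- function(grid, row, col) {
  cbind(
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size
  )
}

#' @rdname cell_of
#' @return \code{cell_centroids}: data.frame of all cells with columns
#'   \code{row}, \code{col}, \code{x}, \code{y} in row-major order.
#' @export
cell_centroids <- function(grid) {
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  xy <- cell_centroid(grid, row, col)
  data.frame(row = row, col = col, x = xy[, 1], y = xy[, 2])
}

#' @rdname cell_of
#' @return \code{cell_area_km2}: area of one cell in square kilometres.
#' @export
cell_area_km2 <- function(grid) (grid$cell_size / 1000)^2

#' Planar polygon area in square kilometres
#'
#' Area of a simple (non-self-intersecting) polygon given in planar metres,
#' by the shoelace formula. The result does not depend on vertex orientation
#' or on whether the ring is explicitly closed.
#'
#' @param polygon two-column matrix of vertex \code{x}, \code{y} in metres.
#' @return Non-negative area in square kilometres.
#' @examples
#' area_km2(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
#' @export
area_km2 <- function(polygon) {
  p <- as.matrix(polygon)
  if (ncol(p) != 2 || nrow(p) < 3)
    stop("polygon must be a two-column matrix with at least 3 vertices",
         call. = FALSE)
  if (any(!is.finite(p))) stop("polygon has non-finite vertices", call. = FALSE)
  # drop an explicit closing vertex
  if (isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE)))
    p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3)
    stop("geometry error: degenerate ring (fewer than 3 distinct vertices)",
         call. = FALSE)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2 / 1e6
}

#' Raster layer on a grid
#'
#' A matrix of cell values bound to a \code{\link{grid_spec}} (row 1 =
#' northernmost row). Cells equal to \code{nodata} are excluded from every
#' aggregate the package computes.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param values numeric matrix with \code{n_rows} x \code{n_cols} entries.
#' @param nodata sentinel for missing cells (default -9999).
#' @return An object of class \code{raster_layer}.
#' @export
raster_layer <- function(grid, values, nodata = -9999) {
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values shape does not match grid (", grid$n_rows, " x ",
         grid$n_cols, ")", call. = FALSE)
  structure(list(grid = grid, values = values, nodata = nodata),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[x$values != x$nodata]
  cat(sprintf("<raster_layer> %d x %d (%s); value range [%g, %g], %d nodata\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$crs$id,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(x$values == x$nodata)))
  invisible(x)
}

#' Sample raster values at planar points
#'
#' @param raster a \code{\link{raster_layer}}.
#' @param x,y planar coordinates in metres.
#' @return Numeric vector of cell values; \code{NA} outside the extent or on
#'   nodata cells.
#' @export
raster_value_at <- function(raster, x, y) {
  rc <- cell_of(raster$grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  idx <- cbind(rc$row[ok], rc$col[ok])
  v <- raster$values[idx]
  v[v == raster$nodata] <- NA_real_
  out[ok] <- v
  out
}

#' Resample a raster to another grid (nearest neighbour)
#'
#' Nearest-neighbour resampling: each target cell takes the value of the
#' source cell containing its centroid. Nearest neighbour is deliberate --
#' reflectance values are quantized categories used by an exact-matching
#' rule, and interpolation would invent values.
#'
#' @param raster source \code{\link{raster_layer}}.
#' @param grid target \code{\link{grid_spec}} (same CRS).
#' @return A \code{raster_layer} on \code{grid}; uncovered cells are nodata.
#' @export
resample_nearest <- function(raster, grid) {
  if (!identical(raster$grid$crs$id, grid$crs$id))
    stop("resample_nearest: source and target CRS differ", call. = FALSE)
  if (grids_aligned(raster$grid, grid)) return(raster_layer(grid, raster$values, raster$nodata))
  cc <- cell_centroids(grid)
  v <- raster_value_at(raster, cc$x, cc$y)
  v[is.na(v)] <- raster$nodata
  raster_layer(grid, matrix(v, grid$n_rows, grid$n_cols, byrow = TRUE),
               raster$nodata)
}

#' Point-in-polygon test
#'
#' Even-odd ray-casting test for planar points against a simple polygon ring.
#'
#' @param x,y planar point coordinates (equal-length vectors).
#' @param polygon two-column vertex matrix (open or closed ring).
#' @return Logical vector; boundary points may fall either way.
#' @export
point_in_polygon <- function(x, y, polygon) {
  p <- as.matrix(polygon)
  if (isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE)))
    p <- p[-nrow(p), , drop = FALSE]
  n <- nrow(p)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]; xj <- p[j, 1]; yj <- p[j, 2]
    cross <- (yi > y) != (yj > y)
    xint <- (xj - xi) * (y - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & (x < xint))
    j <- i
  }
  inside
}
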