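# Habitat prediction by environmental value matching. For each sighting day,
# all pixels of the daily reflectance raster sharing the value observed at
# the sighting pixels are selected ("same-value" matching on the quantized
# product); the union across days, constrained by bathymetry, is the habitat
# area, and per-day layers are stacked into the potential-distribution index.

#' Daily habitat layer from same-value reflectance matching
#'
#' Builds one day's habitat mask: the union, over that day's matched
#' sightings, of all raster pixels whose reflectance value is within
#' \code{tolerance} of the value at the sighting pixel. The default tolerance
#' 0 is exact equality, which is meaningful because the reflectance product
#' is integer-quantized. Nodata pixels are never masked; sightings landing on
#' nodata pixels are skipped with a warning, and a layer where every sighting
#' does so is an error.
#'
#' @param sightings matched sighting records of a single date (rows with
#'   \code{matched}, \code{lat}, \code{lon}, \code{date}).
#' @param reflectance a \code{\link{raster_layer}} of that day's quantized
#'   reflectance.
#' @param tolerance half-width of the value-matching band, in raster value
#'   units (default 0 = exact).
#' @return An object of class \code{daily_habitat_layer}: list with
#'   \code{date}, logical \code{mask} on the raster grid,
#'   \code{source_values}, \code{grid}.
#' @export
daily_layer <- function(sightings, reflectance, tolerance = 0) {
  s <- sightings[sightings$matched %in% TRUE, , drop = FALSE]
  if (nrow(s) == 0) stop("daily_layer: no matched sightings", call. = FALSE)
  d <- unique(as.character(s$date))
  if (length(d) != 1)
    stop("daily_layer: sightings span several dates: ",
         paste(d, collapse = ", "), call. = FALSE)
  xy <- project(cbind(s$lon, s$lat), reflectance$grid$crs)
  vals <- raster_value_at(reflectance, xy[, 1], xy[, 2])
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " sighting(s) on ", d,
            " fall on nodata or outside the raster; skipped", call. = FALSE)
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals))
    stop("empty daily layer on ", d,
         ": every sighting fell on nodata pixels", call. = FALSE)
  vals <- sort(unique(vals))
  V <- reflectance$values
  ok <- V != reflectance$nodata
  mask <- matrix(FALSE, nrow(V), ncol(V))
  for (v in vals) mask <- mask | (ok & abs(V - v) <= tolerance)
  structure(list(date = as.Date(d), mask = mask, source_values = vals,
                 grid = reflectance$grid),
            class = "daily_habitat_layer")
}

#' @export
print.daily_habitat_layer <- function(x, ...) {
  cat(sprintf("<daily_habitat_layer> %s: %d masked pixels, values {%s}\n",
              format(x$date), sum(x$mask),
              paste(x$source_values, collapse = ", ")))
  invisible(x)
}

#' Constrain a habitat layer by bathymetry
#'
#' Removes habitat cells deeper than \code{depth_limit}; depth is a physical
#' barrier to coastal turtle distribution. The bathymetry is resampled to the
#' layer grid (nearest neighbour) if not co-registered; bathymetry nodata
#' over masked cells is an error because the constraint would be undefined
#' there.
#'
#' @param layer a \code{daily_habitat_layer} or \code{habitat_area}.
#' @param bathymetry \code{\link{raster_layer}} of depths in metres
#'   (positive down by default).
#' @param depth_limit metres; cells deeper than this are removed (default 50).
#' @param depth_sign 1 for positive-down depths, -1 for negative-down.
#' @return Object of the same class with \code{mask} intersected with the
#'   depth constraint (output mask is a subset of the input mask).
#' @export
apply_bathymetry <- function(layer, bathymetry, depth_limit = 50,
                             depth_sign = 1) {
  b <- resample_nearest(bathymetry, layer$grid)
  depth <- b$values * depth_sign
  covered <- b$values != b$nodata
  if (any(layer$mask & !covered))
    stop("bathymetry has nodata over ", sum(layer$mask & !covered),
         " masked habitat cell(s); the depth constraint is undefined there",
         call. = FALSE)
  layer$mask <- layer$mask & covered & depth <= depth_limit
  layer
}

#' Stack daily layers into the potential-distribution index
#'
#' Counts, for every cell of the analysis grid, how many daily habitat layers
#' cover it: pixels of each daily mask are reduced to their centroids and a
#' layer contributes at most 1 per cell regardless of how many of its pixels
#' fall inside (each day is one piece of evidence). The per-cell sum across
#' days is the potential-distribution index, bounded by the number of layers
#' stacked.
#'
#' @param layers list of \code{daily_habitat_layer} objects.
#' @param grid target \code{\link{grid_spec}} (the 1-km analysis lattice).
#' @return Object of class \code{potential_distribution}: list with
#'   \code{grid}, integer matrix \code{index}, \code{n_layers}.
#' @export
stack_layers <- function(layers, grid) {
  if (!length(layers)) stop("stack_layers: empty layer list", call. = FALSE)
  index <- matrix(0L, grid$n_rows, grid$n_cols)
  for (ly in layers) {
    if (!identical(ly$grid$crs$id, grid$crs$id))
      stop("stack_layers: layer CRS differs from grid CRS", call. = FALSE)
    w <- which(ly$mask, arr.ind = TRUE)
    if (!nrow(w)) next
    cen <- cell_centroid(ly$grid, w[, 1], w[, 2])
    rc <- cell_of(grid, cen[, 1], cen[, 2])
    rc <- unique(rc[!is.na(rc$row), , drop = FALSE])
    if (nrow(rc))
      index[cbind(rc$row, rc$col)] <- index[cbind(rc$row, rc$col)] + 1L
  }
  structure(list(grid = grid, index = index, n_layers = length(layers)),
            class = "potential_distribution")
}

#' @export
print.potential_distribution <- function(x, ...) {
  cat(sprintf("<potential_distribution> %d layers stacked; index range 0-%d on %d x %d grid\n",
              x$n_layers, max(x$index), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Habitat area: bathymetry-constrained union of daily layers
#'
#' The habitat area is the union (not the sum) of the daily habitat
#' footprints after removing cells deeper than \code{depth_limit}. Total area
#' and the areas within each configured isobath (default 20 m and 50 m, the
#' management depths) are reported in square kilometres.
#'
#' @inheritParams apply_bathymetry
#' @param layers list of \code{daily_habitat_layer} objects on one grid.
#' @param strata isobaths (metres) at which to report area (default 20, 50).
#' @return Object of class \code{habitat_area}: list with \code{grid},
#'   logical \code{mask}, \code{total_km2}, named \code{depth_strata_km2}.
#' @export
habitat_area <- function(layers, bathymetry, depth_limit = 50,
                         strata = c(20, 50), depth_sign = 1) {
  if (!length(layers)) stop("habitat_area: empty layer list", call. = FALSE)
  g <- layers[[1]]$grid
  for (ly in layers)
    if (!grids_aligned(ly$grid, g))
      stop("habitat_area: daily layers are on different grids", call. = FALSE)
  masked <- lapply(layers, apply_bathymetry, bathymetry = bathymetry,
                   depth_limit = depth_limit, depth_sign = depth_sign)
  union <- Reduce(`|`, lapply(masked, `[[`, "mask"))
  b <- resample_nearest(bathymetry, g)
  depth <- b$values * depth_sign
  strata_km2 <- vapply(strata, function(s)
    sum(union & b$values != b$nodata & depth <= s) * cell_area_km2(g),
    numeric(1))
  names(strata_km2) <- paste0("within_", strata, "m")
  structure(list(grid = g, mask = union,
                 total_km2 = sum(union) * cell_area_km2(g),
                 depth_strata_km2 = strata_km2,
                 depth_limit = depth_limit),
            class = "habitat_area")
}

#' @export
print.habitat_area <- function(x, ...) {
  cat(sprintf("<habitat_area> %.2f km2 within %g m depth (%s)\n",
              x$total_km2, x$depth_limit,
              paste(sprintf("%s: %.2f km2", names(x$depth_strata_km2),
                            x$depth_strata_km2), collapse = "; ")))
  invisible(x)
}

#' Cell rectangles of a mask, as polygons
#'
#' Utility used when exporting habitat masks to GeoJSON: each masked cell
#' becomes its square outline in planar metres.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param mask logical matrix on \code{grid}.
#' @return List of 4-vertex matrices (one per masked cell, row-major order).
#' @export
mask_polygons <- function(grid, mask) {
  w <- which(t(mask), arr.ind = TRUE)  # row-major order
  if (!nrow(w)) return(list())
  col <- w[, 1]; row <- w[, 2]
  cs <- grid$cell_size
  lapply(seq_along(row), function(i) {
    x0 <- grid$origin_x + (col[i] - 1) * cs
    y0 <- grid$origin_y + (grid$n_rows - row[i]) * cs
    cbind(x = c(x0, x0 + cs, x0 + cs, x0), y = c(y0, y0, y0 + cs, y0 + cs))
  })
}
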