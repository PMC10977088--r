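# Plain-text geospatial I/O: ESRI ASCII grids for rasters, GeoJSON for
# vector layers. Integer layers round-trip bit-exactly through the ASCII
# grid format; GeoJSON coordinates are WGS84-style lon/lat obtained by
# unprojecting the metric analysis coordinates.

#' Read and write ESRI ASCII grid rasters
#'
#' The ASCII grid (.asc) format carries georeferencing (lower-left corner,
#' cell size, nodata sentinel) in a six-line header followed by rows of cell
#' values from north to south. Integer layers are written as integers and so
#' round-trip exactly.
#'
#' @param path file path.
#' @param crs CRS to attach on read (the format itself carries none).
#' @return \code{read_asc}: a \code{\link{raster_layer}}.
#' @export
read_asc <- function(path, crs = utm_crs(25, TRUE)) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ASCII grid header, missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$nrows * hdr$ncols, call. = FALSE)
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                 hdr$nrows, hdr$ncols, crs)
  raster_layer(g, matrix(vals, hdr$nrows, hdr$ncols, byrow = TRUE), nodata)
}

#' @rdname read_asc
#' @param raster a \code{\link{raster_layer}} to write.
#' @param digits significant digits for non-integer layers.
#' @export
write_asc <- function(raster, path, digits = 10) {
  g <- raster$grid
  v <- raster$values
  is_int <- all(v == round(v))
  fmt <- function(row) {
    if (is_int) paste(formatC(row, format = "d"), collapse = " ")
    else paste(formatC(row, format = "g", digits = digits), collapse = " ")
  }
  body <- vapply(seq_len(g$n_rows), function(r) fmt(v[r, ]), character(1))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.6f", g$origin_x),
    sprintf("yllcorner %.6f", g$origin_y),
    sprintf("cellsize %.6f", g$cell_size),
    sprintf("NODATA_value %s",
            formatC(raster$nodata, format = if (is_int) "d" else "g")),
    body
  ), path)
  invisible(path)
}

.geojson_feature <- function(geometry, properties) {
  list(type = "Feature",
       geometry = geometry,
       properties = if (length(properties)) properties else structure(list(), names = character(0)))
}

.geojson_write <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Write point and polygon layers as GeoJSON
#'
#' Geometries given in planar metres are unprojected back to lon/lat before
#' writing (GeoJSON is a geographic format). Each row/polygon becomes one
#' Feature carrying the remaining columns (or supplied list) as properties.
#'
#' @param points data.frame with planar \code{x}, \code{y} columns; all other
#'   columns become feature properties.
#' @param path output file path.
#' @param crs the metric CRS the coordinates are in.
#' @export
write_geojson_points <- function(points, path, crs) {
  crs <- as_crs(crs)
  ll <- unproject(cbind(points$x, points$y), crs)
  props <- points[, setdiff(names(points), c("x", "y")), drop = FALSE]
  feats <- lapply(seq_len(nrow(points)), function(i) {
    .geojson_feature(
      list(type = "Point", coordinates = c(ll[i, 1], ll[i, 2])),
      as.list(props[i, , drop = FALSE])
    )
  })
  .geojson_write(feats, path)
}

#' @rdname write_geojson_points
#' @param polygons list of two-column vertex matrices (planar metres, open or
#'   closed rings), one polygon per feature.
#' @param properties optional list of per-polygon property lists (same length
#'   as \code{polygons}).
#' @export
write_geojson_polygons <- function(polygons, path, crs, properties = NULL) {
  crs <- as_crs(crs)
  feats <- lapply(seq_along(polygons), function(i) {
    ring <- as.matrix(polygons[[i]])
    if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE)))
      ring <- rbind(ring, ring[1, ])
    ll <- unproject(ring, crs)
    coords <- lapply(seq_len(nrow(ll)), function(j) c(ll[j, 1], ll[j, 2]))
    .geojson_feature(
      list(type = "Polygon", coordinates = list(coords)),
      if (is.null(properties)) list() else properties[[i]]
    )
  })
  .geojson_write(feats, path)
}
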