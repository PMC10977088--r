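# Risk of turtle-fishery interaction: the product of the log10-scaled
# potential-distribution index and fishing intensity, computed on the shared
# 1-km grid and spread over the habitat area by inverse-distance weighting.

#' Risk-of-interaction scores on the shared grid
#'
#' For every cell of the common lattice, computes
#' \code{log10(pd + 1) * log10(fi + 1)}: both factors are put on a base-10
#' logarithmic scale (with the +1 constant so zero cells stay defined and
#' score 0) so distribution and intensity carry the same weight in the
#' product. The two layers must be on the identical grid; nothing is
#' resampled silently.
#'
#' @param pd a \code{potential_distribution} (see \code{\link{stack_layers}}).
#' @param fi a \code{fishing_intensity} (see \code{\link{intensity_grid}}).
#' @return data.frame with one row per cell: \code{row}, \code{col},
#'   \code{x}, \code{y} (centroid, metres), \code{pd}, \code{fi},
#'   \code{score}.
#' @export
risk_score <- function(pd, fi) {
  if (!grids_aligned(pd$grid, fi$grid))
    stop("alignment error: potential distribution and fishing intensity are ",
         "not on the same grid (no silent resampling)", call. = FALSE)
  cc <- cell_centroids(pd$grid)
  cc$pd <- as.vector(t(pd$index))
  cc$fi <- as.vector(t(fi$trips_per_cell))
  cc$score <- log10(cc$pd + 1) * log10(cc$fi + 1)
  cc
}

#' Inverse-distance-weighted interpolation
#'
#' Shepard interpolation: the value at a target point is the weighted mean of
#' sample values with weights \code{d^(-power)}. A target coincident with a
#' sample takes the sample value exactly; consequently interpolated values
#' always lie within the range of the sample values. Duplicate sample
#' locations with conflicting values are an error.
#'
#' @param samples data.frame with planar \code{x}, \code{y}, \code{value}.
#' @param targets data.frame (or matrix) with planar \code{x}, \code{y}.
#' @param power positive distance-decay exponent (default 2).
#' @param neighbors \code{"all"} (default) or an integer k: interpolate from
#'   the k nearest samples only.
#' @return Numeric vector of interpolated values, one per target row.
#' @examples
#' s <- data.frame(x = c(0, 10), y = c(0, 0), value = c(0, 1))
#' idw_extrapolate(s, data.frame(x = 5, y = 0))
#' @export
idw_extrapolate <- function(samples, targets, power = 2, neighbors = "all") {
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 2)
  tx <- if (is.data.frame(targets)) targets$x else targets[, 1]
  ty <- if (is.data.frame(targets)) targets$y else targets[, 2]
  if (!nrow(samples)) stop("idw_extrapolate: zero samples", call. = FALSE)
  stopifnot(power > 0)
  key <- paste(samples$x, samples$y)
  if (anyDuplicated(key)) {
    agg <- tapply(samples$value, key, function(v) diff(range(v)))
    if (any(agg > 1e-12))
      stop("duplicate sample points with conflicting values", call. = FALSE)
    samples <- samples[!duplicated(key), , drop = FALSE]
  }
  k <- if (identical(neighbors, "all")) nrow(samples)
       else min(as.integer(neighbors), nrow(samples))
  out <- numeric(length(tx))
  for (i in seq_along(tx)) {
    d2 <- (samples$x - tx[i])^2 + (samples$y - ty[i])^2
    hit <- which(d2 < 1e-12)
    if (length(hit)) { out[i] <- samples$value[hit[1]]; next }
    use <- if (k < nrow(samples)) order(d2)[seq_len(k)] else seq_along(d2)
    w <- d2[use]^(-power / 2)
    out[i] <- sum(w * samples$value[use]) / sum(w)
  }
  out
}

#' Risk surface over the habitat area
#'
#' Computes risk scores where fishing was observed (cells with at least one
#' trip), then spreads them over every habitat-area cell centroid by IDW.
#' The surface is confined to the habitat area: cells outside it are nodata.
#'
#' @inheritParams risk_score
#' @inheritParams idw_extrapolate
#' @param habitat a \code{habitat_area} on the same grid.
#' @return Object of class \code{risk_surface}: list with \code{raster}
#'   (\code{\link{raster_layer}}, nodata outside habitat), \code{samples}
#'   (the scored source cells), \code{power}, \code{neighbors}.
#' @export
risk_surface <- function(pd, fi, habitat, power = 2, neighbors = "all") {
  if (!grids_aligned(pd$grid, habitat$grid))
    stop("alignment error: habitat area is not on the risk grid", call. = FALSE)
  scores <- risk_score(pd, fi)
  samples <- scores[scores$fi > 0, c("x", "y", "score"), drop = FALSE]
  names(samples)[3] <- "value"
  if (!nrow(samples))
    stop("risk_surface: no cells with observed fishing intensity", call. = FALSE)
  cc <- cell_centroids(habitat$grid)
  inhab <- as.vector(t(habitat$mask))
  vals <- matrix(-9999, habitat$grid$n_rows, habitat$grid$n_cols)
  tgt <- cc[inhab, , drop = FALSE]
  if (nrow(tgt)) {
    v <- idw_extrapolate(samples, tgt, power = power, neighbors = neighbors)
    vals[cbind(tgt$row, tgt$col)] <- v
  }
  structure(list(raster = raster_layer(habitat$grid, vals, nodata = -9999),
                 samples = samples, power = power, neighbors = neighbors),
            class = "risk_surface")
}

#' @export
print.risk_surface <- function(x, ...) {
  v <- x$raster$values[x$raster$values != x$raster$nodata]
  cat(sprintf("<risk_surface> %d habitat cells, score range [%.4f, %.4f] from %d samples (IDW power %g)\n",
              length(v), if (length(v)) min(v) else NA,
              if (length(v)) max(v) else NA, nrow(x$samples), x$power))
  invisible(x)
}

#' Equal-interval classification for cartography
#'
#' Classifies a risk raster into equal-interval classes (1 = lowest) for
#' styled mapping; nodata stays nodata.
#'
#' @param raster a \code{\link{raster_layer}}.
#' @param n_classes number of classes (default 5).
#' @return A \code{raster_layer} of integer class codes.
#' @export
classify_equal_interval <- function(raster, n_classes = 5) {
  v <- raster$values
  ok <- v != raster$nodata
  rng <- range(v[ok])
  cls <- v
  if (diff(rng) == 0) {
    cls[ok] <- 1
  } else {
    cls[ok] <- pmin(n_classes, 1 + floor((v[ok] - rng[1]) / diff(rng) * n_classes))
  }
  raster_layer(raster$grid, cls, raster$nodata)
}
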