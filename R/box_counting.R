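# Box-counting fractal dimension of a 3D binary mask.

#' Default box-counting scale schedule
#'
#' Powers of 2 from 1 voxel up to a quarter of the smallest bounding-box
#' dimension, so that at least four boxes span every axis at the coarsest
#' scale.
#'
#' @param mask A [binary_mask()].
#' @return Integer vector of box edge lengths (voxels).
#' @export
default_box_scales <- function(mask) {
  bb <- crop_to_bbox(mask)
  smax <- max(1L, min(dim(bb$occupancy)) %/% 4L)
  scales <- 2^(0:floor(log2(smax)))
  as.integer(scales)
}

# Number of grid-aligned boxes of edge `s` (anchored at the occupied
# bounding-box corner) containing at least one occupied voxel.
.box_count <- function(coords0, s) {
  cells <- coords0 %/% as.integer(s)
  k1 <- max(cells[, 1]) + 1
  k2 <- max(cells[, 2]) + 1
  key <- cells[, 1] + k1 * (cells[, 2] + k2 * cells[, 3])
  length(unique(key))
}

#' Box-counting fractal dimension
#'
#' Covers the occupied set with a grid of cubic boxes of edge `s` voxels,
#' anchored at the corner of the occupied bounding box, and counts the boxes
#' `N(s)` containing at least one occupied voxel. The dimension estimate is
#' the least-squares slope of `log N(s)` against `log(1/s)` over the fit
#' range. Assumes (approximately) cubic voxels; resample anisotropic masks
#' with [resample_isotropic()] first.
#'
#' @param mask A non-empty [binary_mask()].
#' @param scales Strictly increasing integer box edges (voxels); default
#'   [default_box_scales()].
#' @param fit_range Length-2 numeric `(min_scale, max_scale)` delimiting the
#'   scales entering the regression; default spans all `scales`.
#' @return A list of class `fractal_estimate`: `estimate` (the slope),
#'   `curve` (data.frame `scale`, `value` = N(s), `in_fit`), and
#'   `diagnostics` (`r_squared`, `fit_range`).
#' @export
#' @examples
#' cube <- generate_phantom(phantom_spec("filled_cube", size = 32))
#' box_counting_dimension(cube, scales = c(1, 2, 4, 8))$estimate  # 3
box_counting_dimension <- function(mask, scales = default_box_scales(mask),
                                   fit_range = range(scales)) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask", call. = FALSE)
  coords <- mask_coords(mask)
  if (nrow(coords) == 0L) {
    stop("box-counting dimension is undefined for an empty mask", call. = FALSE)
  }
  scales <- as.integer(scales)
  if (any(diff(scales) <= 0) || any(scales < 1L)) {
    stop("`scales` must be strictly increasing positive integers", call. = FALSE)
  }
  lo <- apply(coords, 2L, min)
  coords0 <- sweep(coords, 2L, lo)            # 0-based, anchored at bbox corner
  counts <- vapply(scales, function(s) .box_count(coords0, s), numeric(1))
  in_fit <- scales >= fit_range[1] & scales <= fit_range[2]
  if (sum(in_fit) < 3L) {
    stop("need at least 3 scales inside `fit_range` (got ", sum(in_fit), ")",
         call. = FALSE)
  }
  x <- log(1 / scales[in_fit])
  y <- log(counts[in_fit])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(
    estimate = slope,
    curve = data.frame(scale = scales, value = counts, in_fit = in_fit),
    diagnostics = list(r_squared = r2, fit_range = fit_range)
  ), class = "fractal_estimate")
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat(sprintf("<fractal_estimate> %.4f (R^2 %.4f over %d scales)\n",
              x$estimate,
              if (is.null(x$diagnostics$r_squared)) NA else x$diagnostics$r_squared,
              sum(x$curve$in_fit)))
  invisible(x)
}
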