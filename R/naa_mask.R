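# Attenuation windowing: the normal attenuation area (NAA) of the lung.

#' Normal-attenuation window in Hounsfield units
#'
#' The attenuation window defining normally aerated lung parenchyma. The
#' lower bound is exclusive and the upper bound inclusive: a voxel belongs to
#' the NAA when `lower_hu < HU <= upper_hu`. Defaults (-950, -700] separate
#' normally aerated tissue from emphysema-like low attenuation (<= -950 HU)
#' and from consolidation or soft tissue (> -700 HU).
#'
#' @param lower_hu Exclusive lower bound (default -950).
#' @param upper_hu Inclusive upper bound (default -700).
#' @return An object of class `naa_window`.
#' @export
naa_window <- function(lower_hu = -950, upper_hu = -700) {
  stopifnot_scalar_number(lower_hu, "lower_hu")
  stopifnot_scalar_number(upper_hu, "upper_hu")
  if (!(lower_hu < upper_hu)) {
    stop("`lower_hu` must be strictly below `upper_hu`", call. = FALSE)
  }
  structure(list(lower_hu = lower_hu, upper_hu = upper_hu),
            class = "naa_window")
}

#' Compute the normal-attenuation-area mask
#'
#' Intersects the lung segmentation with the attenuation window: a voxel is
#' kept iff it lies inside the lung mask and its HU value satisfies
#' `lower_hu < HU <= upper_hu` (lower bound exclusive, upper inclusive).
#' All fractal metrics in this package are computed on this mask.
#'
#' @param ct A [ct_volume()].
#' @param lung A [binary_mask()] with the same grid dimensions as `ct`.
#' @param window An [naa_window()]; defaults to (-950, -700].
#' @return A [binary_mask()] with `ct`'s geometry.
#' @export
#' @examples
#' hu <- array(-800, dim = c(4, 4, 4))
#' ct <- ct_volume(hu)
#' lung <- binary_mask(array(TRUE, dim = c(4, 4, 4)))
#' sum(make_naa_mask(ct, lung)$occupancy)  # 64: all voxels in-window
make_naa_mask <- function(ct, lung, window = naa_window()) {
  if (!inherits(ct, "ct_volume")) stop("`ct` must be a ct_volume", call. = FALSE)
  if (!inherits(lung, "binary_mask")) stop("`lung` must be a binary_mask", call. = FALSE)
  if (!inherits(window, "naa_window")) stop("`window` must be an naa_window", call. = FALSE)
  if (!identical(dim(ct$hu), dim(lung$occupancy))) {
    stop(sprintf("geometry mismatch: CT is %s but lung mask is %s",
                 paste(dim(ct$hu), collapse = "x"),
                 paste(dim(lung$occupancy), collapse = "x")), call. = FALSE)
  }
  occ <- lung$occupancy & (ct$hu > window$lower_hu) & (ct$hu <= window$upper_hu)
  binary_mask(occ, ct$spacing)
}
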