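# Per-scan fractal profiles and pre/post deltas.

#' Settings for fractal profile extraction
#'
#' Collects every tunable of the three estimators so a profile records
#' exactly how it was produced.
#'
#' @param target_mm Isotropic voxel edge (mm) for the cube-grid metrics
#'   (box counting, lacunarity); masks already isotropic at `target_mm` are
#'   used as-is. Default 1 mm.
#' @param box_scales,box_fit_range Passed to [box_counting_dimension()];
#'   `NULL` means the default power-of-2 schedule over the full range.
#' @param lacunarity_sizes Passed to [lacunarity()]; `NULL` means
#'   `c(2, 4, 8, 16)` voxels truncated to the mask.
#' @param mst_sizes,mst_reps Passed to [mst_fractal_dimension()]; `NULL`
#'   sizes mean the default schedule truncated to the occupied count.
#' @param seed Mandatory integer seed (MST subsampling).
#' @return A list of class `fractal_settings`.
#' @export
fractal_settings <- function(target_mm = 1, box_scales = NULL,
                             box_fit_range = NULL, lacunarity_sizes = NULL,
                             mst_sizes = NULL, mst_reps = 10, seed = NULL) {
  if (is.null(seed)) {
    stop("`seed` is mandatory in fractal_settings (MST subsampling is stochastic)",
         call. = FALSE)
  }
  structure(list(target_mm = target_mm, box_scales = box_scales,
                 box_fit_range = box_fit_range,
                 lacunarity_sizes = lacunarity_sizes,
                 mst_sizes = mst_sizes, mst_reps = mst_reps,
                 seed = as.integer(seed)),
            class = "fractal_settings")
}

#' Fractal profile of a single mask
#'
#' Computes the three morphometric complexity biomarkers of one binary
#' mask: box-counting fractal dimension and gliding-box lacunarity on the
#' isotropically resampled, bounding-box-cropped mask, and the MST fractal
#' dimension on the physical mm coordinates of the original voxels (the MST
#' needs only pairwise distances, so no resampling).
#'
#' @param mask A non-empty [binary_mask()].
#' @param settings A [fractal_settings()].
#' @return An object of class `fractal_profile` with fields `boxfd`,
#'   `lacunarity`, `mstfd`, and `diagnostics` (fit quality, scale sets,
#'   seed, settings).
#' @export
fractal_profile <- function(mask, settings) {
  if (!inherits(settings, "fractal_settings")) {
    stop("`settings` must be a fractal_settings object", call. = FALSE)
  }
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask", call. = FALSE)
  if (sum(mask$occupancy) < 2L) {
    stop("mask has fewer than 2 occupied voxels; fractal metrics undefined",
         call. = FALSE)
  }
  iso <- resample_isotropic(mask, settings$target_mm)
  iso <- crop_to_bbox(iso)
  bx <- if (is.null(settings$box_scales)) {
    sc <- default_box_scales(iso)
    if (is.null(settings$box_fit_range)) {
      box_counting_dimension(iso, scales = sc)
    } else {
      box_counting_dimension(iso, scales = sc, fit_range = settings$box_fit_range)
    }
  } else if (is.null(settings$box_fit_range)) {
    box_counting_dimension(iso, scales = settings$box_scales)
  } else {
    box_counting_dimension(iso, scales = settings$box_scales,
                           fit_range = settings$box_fit_range)
  }
  lac <- lacunarity(iso, box_sizes = settings$lacunarity_sizes)
  mst <- mst_fractal_dimension(mask, subsample_sizes = settings$mst_sizes,
                               reps = settings$mst_reps, seed = settings$seed)
  structure(list(
    boxfd = bx$estimate,
    lacunarity = lac$estimate,
    mstfd = mst$estimate,
    diagnostics = list(
      box_curve = bx$curve, box_r_squared = bx$diagnostics$r_squared,
      lacunarity_curve = lac$curve,
      mst_curve = mst$curve, mst_slope = mst$diagnostics$slope,
      mst_flagged = mst$diagnostics$flagged_out_of_range,
      settings = settings
    )
  ), class = "fractal_profile")
}

#' @export
print.fractal_profile <- function(x, ...) {
  cat(sprintf("<fractal_profile> BoxFD %.4f | Lacunarity %.4f | MSTFD %.4f\n",
              x$boxfd, x$lacunarity, x$mstfd))
  invisible(x)
}

#' Pre/post fractal profiles and their differences
#'
#' Computes a [fractal_profile()] for the pre- and post-treatment masks of
#' one patient and the post-minus-pre difference of each biomarker
#' (delta features), the longitudinal predictors used downstream.
#'
#' @param pre_mask,post_mask Non-empty [binary_mask()] objects.
#' @param settings A [fractal_settings()].
#' @return A list of class `profile_pair`: `pre`, `post`
#'   ([fractal_profile()]s) and `delta` (class `delta_profile` with
#'   `d_boxfd`, `d_lacunarity`, `d_mstfd`, each exactly post minus pre).
#' @export
compute_profile <- function(pre_mask, post_mask, settings) {
  pre <- fractal_profile(pre_mask, settings)
  post <- fractal_profile(post_mask, settings)
  delta <- structure(list(
    d_boxfd = post$boxfd - pre$boxfd,
    d_lacunarity = post$lacunarity - pre$lacunarity,
    d_mstfd = post$mstfd - pre$mstfd
  ), class = "delta_profile")
  structure(list(pre = pre, post = post, delta = delta),
            class = "profile_pair")
}
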