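# Fractal phantom generation: binary volumes with analytically known
# complexity, used to verify every estimator in the package.

#' Phantom specification
#'
#' Describes a synthetic binary volume of known structure. Available kinds:
#'
#' * `filled_cube` — every voxel occupied (dimension 3, lacunarity 0).
#' * `plane` — one fully occupied axial slab (dimension 2).
#' * `menger_sponge` — the standard level-`level` Menger sponge on a
#'   `3^level` grid (dimension log 20 / log 3).
#' * `random_dust` / `uniform_points` — exactly
#'   `round(occupancy * size^3)` voxels drawn uniformly without replacement
#'   (dimension 3 for point-set estimators).
#' * `thresholded_field` — Gaussian white noise smoothed to correlation
#'   length `correlation_length` voxels and thresholded at the quantile
#'   giving exactly the target occupancy; the texture model used for
#'   lung-parenchyma-like masks.
#' * `line_points` — voxels on a single axis-aligned line (subset of
#'   fraction `occupancy`; dimension 1).
#' * `plane_points` — voxels of one axial slab (subset of fraction
#'   `occupancy`; dimension 2).
#'
#' @param kind Phantom kind (see above).
#' @param size Voxels per side; the generated grid is `size^3`.
#' @param level Recursion depth, `menger_sponge` only; requires
#'   `size == 3^level`.
#' @param occupancy Target occupied fraction in (0, 1]; used by
#'   `random_dust`, `uniform_points`, `thresholded_field`, `line_points`,
#'   `plane_points`.
#' @param correlation_length Smoothing length in voxels (> 0),
#'   `thresholded_field` only.
#' @param seed Integer seed; mandatory for stochastic kinds.
#' @param spacing Voxel spacing in mm (default isotropic 1 mm).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("filled_cube", "plane", "menger_sponge",
                                  "random_dust", "thresholded_field",
                                  "line_points", "plane_points",
                                  "uniform_points"),
                         size, level = NULL, occupancy = NULL,
                         correlation_length = NULL, seed = NULL,
                         spacing = c(1, 1, 1)) {
  kind <- match.arg(kind)
  stopifnot_scalar_number(size, "size", positive = TRUE)
  if (size != round(size)) stop("`size` must be an integer", call. = FALSE)
  size <- as.integer(size)
  if (kind == "menger_sponge") {
    if (is.null(level) || level < 0 || level != round(level)) {
      stop("menger_sponge requires a non-negative integer `level`", call. = FALSE)
    }
    if (size != 3^level) {
      stop(sprintf("menger_sponge requires size = 3^level (got size %d, level %d)",
                   size, as.integer(level)), call. = FALSE)
    }
  }
  if (!is.null(occupancy)) {
    stopifnot_scalar_number(occupancy, "occupancy", positive = TRUE)
    if (occupancy > 1) stop("`occupancy` must be in (0, 1]", call. = FALSE)
  }
  if (kind %in% c("random_dust", "thresholded_field", "uniform_points") &&
      is.null(occupancy)) {
    stop(kind, " requires `occupancy`", call. = FALSE)
  }
  if (kind == "thresholded_field") {
    if (is.null(correlation_length) || correlation_length <= 0) {
      stop("thresholded_field requires `correlation_length` > 0", call. = FALSE)
    }
  }
  structure(list(kind = kind, size = size,
                 level = if (is.null(level)) NA_integer_ else as.integer(level),
                 occupancy = occupancy,
                 correlation_length = correlation_length,
                 seed = seed, spacing = spacing),
            class = "phantom_spec")
}

# Gaussian-smoothed white noise via FFT with periodic boundary; sd of the
# smoothing kernel = correlation_length voxels.
.smoothed_field <- function(size, correlation_length) {
  z <- array(rnorm(size^3), dim = rep(size, 3L))
  ax <- seq_len(size) - 1L
  ax <- pmin(ax, size - ax)                    # circular distance
  g1 <- exp(-ax^2 / (2 * correlation_length^2))
  kern <- outer(outer(g1, g1), g1)
  kern <- kern / sum(kern)
  Re(fft(fft(z) * fft(kern), inverse = TRUE)) / length(z)
}

# threshold a scalar field so that exactly k voxels are occupied
.threshold_top_k <- function(field, k) {
  cut <- sort(field, decreasing = TRUE, method = "quick")[k]
  occ <- field >= cut
  if (sum(occ) > k) {                          # ties at the cut value
    extra <- which(occ & field == cut)
    occ[extra[seq_len(sum(occ) - k)]] <- FALSE
  }
  occ
}

.menger_occupied <- function(level) {
  # returns logical array of side 3^level by iterated subdivision
  occ <- array(TRUE, dim = c(1L, 1L, 1L))
  for (l in seq_len(level)) {
    s <- dim(occ)[1]
    new <- array(FALSE, dim = rep(3L * s, 3L))
    keep <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
    # drop the 6 face centres and the body centre (keep 20 of 27 children)
    center_count <- (keep$i == 1) + (keep$j == 1) + (keep$k == 1)
    keep <- keep[center_count < 2, ]
    for (r in seq_len(nrow(keep))) {
      new[keep$i[r] * s + seq_len(s), keep$j[r] * s + seq_len(s),
          keep$k[r] * s + seq_len(s)] <- occ
    }
    occ <- new
  }
  occ
}

#' Generate a phantom volume
#'
#' Deterministic for a fixed seed. See [phantom_spec()] for the kinds.
#'
#' @param spec A [phantom_spec()].
#' @return A [binary_mask()] of dimensions `size^3`.
#' @export
#' @examples
#' m <- generate_phantom(phantom_spec("menger_sponge", size = 27, level = 3))
#' sum(m$occupancy)  # 20^3 = 8000
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec", call. = FALSE)
  s <- spec$size
  occ <- switch(spec$kind,
    filled_cube = array(TRUE, dim = rep(s, 3L)),
    plane = {
      a <- array(FALSE, dim = rep(s, 3L))
      a[, , max(1L, s %/% 2L)] <- TRUE
      a
    },
    menger_sponge = .menger_occupied(spec$level),
    random_dust = ,
    uniform_points = with_seed(spec$seed, {
      k <- max(1L, round(spec$occupancy * s^3))
      a <- array(FALSE, dim = rep(s, 3L))
      a[sample.int(s^3, k)] <- TRUE
      a
    }),
    thresholded_field = with_seed(spec$seed, {
      k <- max(1L, round(spec$occupancy * s^3))
      field <- .smoothed_field(s, spec$correlation_length)
      array(.threshold_top_k(field, k), dim = rep(s, 3L))
    }),
    line_points = {
      a <- array(FALSE, dim = rep(s, 3L))
      mid <- max(1L, s %/% 2L)
      idx <- seq_len(s)
      if (!is.null(spec$occupancy) && spec$occupancy < 1) {
        idx <- with_seed(spec$seed,
                         sort(sample(idx, max(2L, round(spec$occupancy * s)))))
      }
      a[idx, mid, mid] <- TRUE
      a
    },
    plane_points = {
      a <- array(FALSE, dim = rep(s, 3L))
      mid <- max(1L, s %/% 2L)
      sl <- matrix(TRUE, s, s)
      if (!is.null(spec$occupancy) && spec$occupancy < 1) {
        sl <- matrix(FALSE, s, s)
        pick <- with_seed(spec$seed,
                          sample.int(s^2, max(2L, round(spec$occupancy * s^2))))
        sl[pick] <- TRUE
      }
      a[, , mid] <- sl
      a
    }
  )
  if (!any(occ)) stop("generated phantom is empty", call. = FALSE)
  binary_mask(occ, spacing = spec$spacing)
}
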