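# Dose-volume histogram predictors over the lung mask.

#' Dose-volume histogram metrics of a lung dose distribution
#'
#' Computes the standard dosimetric pneumonitis predictors from a 3D dose
#' grid (Gy) and a lung mask sharing its geometry: mean lung dose (reported
#' in cGy) and the percent lung volume receiving at least 5, 10 and 20 Gy
#' (inclusive thresholds). Volume is measured by voxel count, which equals
#' physical volume for a uniform-spacing grid.
#'
#' @param dose 3D numeric array of doses in Gy (non-negative, finite), or a
#'   list with fields `dose` and `spacing`.
#' @param lung A non-empty [binary_mask()] with the same grid dimensions.
#' @return A list of class `dvh_metrics`: `mld_cgy`, `v5_pct`, `v10_pct`,
#'   `v20_pct`.
#' @export
#' @examples
#' lung <- binary_mask(array(TRUE, dim = c(4, 4, 4)))
#' dvh_metrics(array(10, dim = c(4, 4, 4)), lung)  # V5=V10=100, V20=0, MLD=1000
dvh_metrics <- function(dose, lung) {
  if (is.list(dose)) dose <- dose$dose
  if (!is.array(dose) || length(dim(dose)) != 3L) {
    stop("`dose` must be a 3D array of Gy values", call. = FALSE)
  }
  if (!all(is.finite(dose)) || any(dose < 0)) {
    stop("doses must be finite and non-negative", call. = FALSE)
  }
  if (!inherits(lung, "binary_mask")) stop("`lung` must be a binary_mask", call. = FALSE)
  if (!identical(dim(dose), dim(lung$occupancy))) {
    stop(sprintf("geometry mismatch: dose grid is %s but lung mask is %s",
                 paste(dim(dose), collapse = "x"),
                 paste(dim(lung$occupancy), collapse = "x")), call. = FALSE)
  }
  d <- dose[lung$occupancy]
  if (length(d) == 0L) stop("lung mask is empty", call. = FALSE)
  vx <- function(x) 100 * mean(d >= x)
  structure(list(mld_cgy = mean(d) * 100,
                 v5_pct = vx(5), v10_pct = vx(10), v20_pct = vx(20)),
            class = "dvh_metrics")
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("<dvh_metrics> MLD %.1f cGy | V5 %.1f%% | V10 %.1f%% | V20 %.1f%%\n",
              x$mld_cgy, x$v5_pct, x$v10_pct, x$v20_pct))
  invisible(x)
}

#' Read per-patient DVH metrics from a planning-system export
#'
#' Expects a CSV with columns `mld_cgy`, `v5_pct`, `v10_pct`, `v20_pct`
#' (plus any identifier columns, preserved). Vx values must lie in
#' \[0, 100\]; violations of the physical monotonicity V5 >= V10 >= V20 —
#' which real plans can only produce through rounding — are reported as
#' warnings, not rejections.
#'
#' @param path CSV path.
#' @return A data.frame of the validated rows.
#' @export
read_dvh_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, check.names = FALSE)
  if (nrow(tab) == 0L) stop("DVH table is empty: ", path, call. = FALSE)
  need <- c("mld_cgy", "v5_pct", "v10_pct", "v20_pct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("DVH table lacks mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cl in need) {
    v <- tab[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("column ", cl, " must be numeric without missing values", call. = FALSE)
    }
  }
  if (any(tab$mld_cgy < 0)) stop("negative MLD values are invalid", call. = FALSE)
  for (cl in c("v5_pct", "v10_pct", "v20_pct")) {
    bad <- tab[[cl]] < 0 | tab[[cl]] > 100
    if (any(bad)) {
      stop(sum(bad), " row(s) have ", cl,
           " outside [0, 100]; percent volumes above 100 are physically impossible",
           call. = FALSE)
    }
  }
  mono_bad <- which(tab$v5_pct < tab$v10_pct | tab$v10_pct < tab$v20_pct)
  if (length(mono_bad)) {
    warning("row(s) ", paste(mono_bad, collapse = ", "),
            " violate V5 >= V10 >= V20 (kept; plausible only via rounding)",
            call. = FALSE)
  }
  tab
}
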