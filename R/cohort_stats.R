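# Descriptive cohort tables and the paired pre/post biomarker comparison.

.q13 <- function(x) unname(quantile(x, c(0.25, 0.75), type = 7))

#' Summarize a patient cohort
#'
#' Produces the descriptive layer of a cohort report: per-group counts with
#' percentages for categorical characteristics, median (range) for
#' continuous ones, and the event rates of pneumonitis grade >= 2 and
#' >= 3. Percentages are computed by exact arithmetic and rendered to
#' `digits` decimals under the chosen rounding convention.
#'
#' @param tab Data.frame with one row per patient; must contain `rp_grade`.
#' @param group_col Optional name of a grouping column (e.g. treatment
#'   group); `NULL` summarizes the whole table as one group.
#' @param percent_mode Rounding convention passed to [percent_value()].
#' @param digits Decimals for percentages (default 1).
#' @return A long data.frame with columns `group`, `characteristic`,
#'   `level`, `n`, `percent`, `median`, `min`, `max` (`NA` where not
#'   applicable).
#' @export
summarize_cohort <- function(tab, group_col = NULL,
                             percent_mode = c("half-up", "half-down", "truncate"),
                             digits = 1) {
  percent_mode <- match.arg(percent_mode)
  if (!is.data.frame(tab) || nrow(tab) == 0L) {
    stop("`tab` must be a non-empty data.frame", call. = FALSE)
  }
  if (!"rp_grade" %in% names(tab)) {
    stop("`tab` must contain an `rp_grade` column", call. = FALSE)
  }
  groups <- if (is.null(group_col)) list(all = tab) else split(tab, tab[[group_col]])
  skip <- c("patient_id", "label", "rp_grade", group_col)
  out <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    n_g <- nrow(sub)
    for (cl in setdiff(names(sub), skip)) {
      v <- sub[[cl]]
      if (is.numeric(v)) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, characteristic = cl, level = NA_character_,
          n = n_g, percent = NA_real_,
          median = median(v), min = min(v), max = max(v))
      } else {
        for (lev in sort(unique(as.character(v)))) {
          k <- sum(as.character(v) == lev)
          out[[length(out) + 1L]] <- data.frame(
            group = g, characteristic = cl, level = lev,
            n = k, percent = percent_value(k / n_g, digits, percent_mode),
            median = NA_real_, min = NA_real_, max = NA_real_)
        }
      }
    }
    for (th in c(2L, 3L)) {
      k <- sum(sub$rp_grade >= th)
      out[[length(out) + 1L]] <- data.frame(
        group = g, characteristic = sprintf("rp_grade_ge%d", th),
        level = NA_character_, n = k,
        percent = percent_value(k / n_g, digits, percent_mode),
        median = NA_real_, min = NA_real_, max = NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Paired pre/post comparison of the fractal biomarkers
#'
#' Builds the comparison report for a cohort of paired profiles: per group
#' and per biomarker, the pre and post median (IQR), the median (IQR) of
#' the post-minus-pre differences, and the Wilcoxon signed-rank p-value
#' ([wilcoxon_signed_rank()]). Raw p-values are reported for the three
#' biomarkers without multiplicity correction. IQRs use linearly
#' interpolated (type-7) percentiles.
#'
#' @param tab Data.frame with columns `<metric>_pre` and `<metric>_post`
#'   for each metric, optionally `patient_id` and a grouping column.
#' @param metrics Biomarker stems (default `boxfd`, `lacunarity`, `mstfd`).
#' @param group_col Optional grouping column name.
#' @param exact_limit,alternative Passed to [wilcoxon_signed_rank()].
#'   `alternative = "greater"` mirrors published paired tables that test
#'   specifically for a post-treatment increase.
#' @return A data.frame with one row per group x metric: medians, IQR
#'   bounds, signed-rank statistic (W+), and p-value.
#' @export
compare_pre_post <- function(tab, metrics = c("boxfd", "lacunarity", "mstfd"),
                             group_col = NULL, exact_limit = 25,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.data.frame(tab) || nrow(tab) == 0L) {
    stop("`tab` must be a non-empty data.frame", call. = FALSE)
  }
  cols <- c(outer(metrics, c("_pre", "_post"), paste0))
  miss <- setdiff(cols, names(tab))
  if (length(miss)) {
    stop("missing paired column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- rowSums(is.na(tab[, cols, drop = FALSE])) > 0
  if (any(bad)) {
    ids <- if ("patient_id" %in% names(tab)) tab$patient_id[bad] else which(bad)
    stop("unpaired patient(s) (missing pre or post value): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  groups <- if (is.null(group_col)) list(all = tab) else split(tab, tab[[group_col]])
  out <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    for (m in metrics) {
      pre <- sub[[paste0(m, "_pre")]]
      post <- sub[[paste0(m, "_post")]]
      tst <- wilcoxon_signed_rank(pre, post, metric_name = m,
                                  exact_limit = exact_limit,
                                  alternative = alternative)
      pq <- .q13(pre); oq <- .q13(post)
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = m, n = length(pre),
        pre_median = median(pre), pre_q1 = pq[1], pre_q3 = pq[2],
        post_median = median(post), post_q1 = oq[1], post_q3 = oq[2],
        diff_median = tst$median_diff,
        diff_q1 = tst$iqr_diff[1], diff_q3 = tst$iqr_diff[2],
        statistic = tst$statistic[["W+"]], p_value = tst$p_value)
    }
  }
  do.call(rbind, out)
}
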