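# Synthetic patient cohorts with planted decision-rule structure.

# Uniform sampling ranges bracketing realistic values for a definitive-RT
# NSCLC cohort: dosimetry in clinical units, fractal biomarkers in the
# ranges observed on lung NAA masks.
.default_feature_ranges <- list(
  age            = c(38, 93),
  mld_cgy        = c(88, 1239),
  v5_pct         = c(5.3, 59.1),
  v10_pct        = c(2.0, 40.0),
  v20_pct        = c(0.4, 21.4),
  boxfd_pre      = c(2.20, 2.42),
  lacunarity_pre = c(0.10, 0.20),
  mstfd_pre      = c(2.69, 2.78),
  d_boxfd        = c(-0.09, 0.05),
  d_lacunarity   = c(-0.02, 0.05),
  d_mstfd        = c(-0.06, 0.02)
)

#' Synthetic cohort specification
#'
#' Describes a patient table whose binary outcome (pneumonitis grade >= 2)
#' follows a planted decision list: rules are evaluated in order and the
#' first rule whose condition `feature > threshold` holds assigns the event
#' probability `p_gt`; if no rule fires the probability is `p_else`. With
#' probabilities all 0/1 and `label_noise = 0` the cohort is perfectly
#' separable by the planted thresholds.
#'
#' @param n_patients Number of rows (>= 2).
#' @param feature_names Features to generate; defaults to all features with
#'   built-in ranges.
#' @param tree_rules List of rules, each `list(feature=, threshold=, p_gt=)`;
#'   thresholds must lie inside the feature's sampling range.
#' @param p_else Event probability when no rule fires (default 0).
#' @param noise_features Count of additional label-independent uniform(0,1)
#'   features named `noise_1`, `noise_2`, ... (default 0).
#' @param label_noise Label flip probability in \[0, 0.5) (default 0).
#' @param feature_ranges Named list of `c(lo, hi)` sampling ranges;
#'   overrides the defaults per feature.
#' @param seed Mandatory integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, feature_names = NULL, tree_rules = list(),
                        p_else = 0, noise_features = 0, label_noise = 0,
                        feature_ranges = NULL, seed = NULL) {
  if (n_patients < 2) stop("`n_patients` must be >= 2", call. = FALSE)
  ranges <- .default_feature_ranges
  if (!is.null(feature_ranges)) ranges[names(feature_ranges)] <- feature_ranges
  if (is.null(feature_names)) feature_names <- names(ranges)
  if (length(feature_names) == 0L) {
    stop("`feature_names` must not be empty", call. = FALSE)
  }
  unknown <- setdiff(feature_names, names(ranges))
  if (length(unknown)) {
    stop("no sampling range for feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("`label_noise` must lie in [0, 0.5)", call. = FALSE)
  }
  for (r in tree_rules) {
    if (!all(c("feature", "threshold", "p_gt") %in% names(r))) {
      stop("each rule needs fields `feature`, `threshold`, `p_gt`", call. = FALSE)
    }
    if (!r$feature %in% feature_names) {
      stop("rule feature not among generated features: ", r$feature, call. = FALSE)
    }
    rg <- ranges[[r$feature]]
    if (r$threshold <= rg[1] || r$threshold >= rg[2]) {
      stop(sprintf("rule threshold %g lies outside the sampling range (%g, %g) of %s",
                   r$threshold, rg[1], rg[2], r$feature), call. = FALSE)
    }
    if (r$p_gt < 0 || r$p_gt > 1) stop("rule `p_gt` must be a probability", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 feature_names = feature_names, tree_rules = tree_rules,
                 p_else = p_else, noise_features = as.integer(noise_features),
                 label_noise = label_noise, feature_ranges = ranges,
                 seed = seed),
            class = "cohort_spec")
}

# event probability of each row under the planted decision list
planted_event_prob <- function(spec, tab) {
  p <- rep(spec$p_else, nrow(tab))
  decided <- rep(FALSE, nrow(tab))
  for (r in spec$tree_rules) {
    fire <- !decided & tab[[r$feature]] > r$threshold
    p[fire] <- r$p_gt
    decided <- decided | fire
  }
  p
}

#' Generate a synthetic patient cohort
#'
#' Deterministic for a fixed seed. Features are sampled uniformly within
#' their ranges; labels follow the planted decision list of the spec, then
#' are flipped independently with probability `label_noise`. The returned
#' table carries an `rp_grade` column (2 for events, 0 otherwise) and the
#' logical outcome `label` (grade >= 2).
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with `patient_id`, the features, `rp_grade`,
#'   `label`; attribute `planted_prob` holds each row's pre-noise event
#'   probability.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_patients
    tab <- data.frame(patient_id = sprintf("P%04d", seq_len(n)))
    for (f in spec$feature_names) {
      rg <- spec$feature_ranges[[f]]
      tab[[f]] <- runif(n, rg[1], rg[2])
    }
    if (spec$noise_features > 0) {
      for (j in seq_len(spec$noise_features)) {
        tab[[paste0("noise_", j)]] <- runif(n)
      }
    }
    p <- planted_event_prob(spec, tab)
    label <- runif(n) < p
    if (spec$label_noise > 0) {
      flip <- runif(n) < spec$label_noise
      label <- xor(label, flip)
    }
    tab$rp_grade <- ifelse(label, 2L, 0L)
    tab$label <- label
    attr(tab, "planted_prob") <- p
    tab
  })
}
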