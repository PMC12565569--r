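# Interpretable pneumonitis risk modeling: random-forest feature ranking
# under cross-validation, a cost-complexity pruned decision tree on the top
# features, and evaluation against the no-information rate.

# stratified fold assignment; assumes the RNG is already seeded
.stratified_folds <- function(label, k) {
  fold <- integer(length(label))
  for (cls in unique(label)) {
    idx <- which(label == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.model_features <- function(tab, features, label_col) {
  if (is.null(features)) {
    features <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                        c("rp_grade", label_col))
  }
  miss <- setdiff(features, names(tab))
  if (length(miss)) {
    stop("feature column(s) absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(tab[, features])) {
    stop("missing feature values are rejected; impute or drop rows upstream",
         call. = FALSE)
  }
  features
}

#' Rank features by random-forest Gini importance under cross-validation
#'
#' Trains one random forest per cross-validation fold (on the training
#' portion) and averages each feature's mean decrease in Gini impurity over
#' the folds. The dispersion across folds is reported alongside.
#'
#' @param tab Patient table with a logical/binary outcome column.
#' @param features Feature column names; default all numeric columns except
#'   `rp_grade` and the label.
#' @param label_col Outcome column (default `"label"`).
#' @param k_folds Cross-validation folds (default 5).
#' @param ntree Trees per forest (default 500).
#' @param mtry Features per split; default `sqrt(p)` rounded down.
#' @param top_k How many leading features to expose as `attr(, "top")`
#'   (default 3).
#' @param seed Mandatory integer seed.
#' @return A data.frame of class `importance_ranking`, descending by
#'   `importance` (mean Gini decrease), with `sd` across folds; attribute
#'   `top` holds the leading `top_k` feature names.
#' @export
rank_features <- function(tab, features = NULL, label_col = "label",
                          k_folds = 5, ntree = 500, mtry = NULL, top_k = 3,
                          seed = NULL) {
  if (nrow(tab) < 20L) {
    stop("need at least 20 rows to rank features", call. = FALSE)
  }
  label <- as.logical(tab[[label_col]])
  if (length(unique(label)) < 2L) {
    stop("outcome has a single class; importance ranking undefined", call. = FALSE)
  }
  features <- .model_features(tab, features, label_col)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  x <- tab[, features, drop = FALSE]
  y <- factor(label, levels = c(FALSE, TRUE))
  imp <- with_seed(seed, {
    fold <- .stratified_folds(label, k_folds)
    vapply(seq_len(k_folds), function(f) {
      tr <- fold != f
      rf <- randomForest::randomForest(x = x[tr, , drop = FALSE], y = y[tr],
                                       ntree = ntree, mtry = mtry)
      rf$importance[features, "MeanDecreaseGini"]
    }, numeric(length(features)))
  })
  res <- data.frame(feature = features,
                    importance = rowMeans(imp),
                    sd = apply(imp, 1L, sd))
  res <- res[order(-res$importance), ]
  rownames(res) <- NULL
  structure(res, class = c("importance_ranking", "data.frame"),
            top = head(res$feature, top_k))
}

# 1-SE cost-complexity choice from an rpart cptable
.cp_one_se <- function(cptable) {
  i_min <- which.min(cptable[, "xerror"])
  thresh <- cptable[i_min, "xerror"] + cptable[i_min, "xstd"]
  i_sel <- which(cptable[, "xerror"] <= thresh)[1L]  # smallest tree within 1 SE
  # geometric midpoint of the cp interval is the conventional pruning value
  if (i_sel == 1L) Inf else
    sqrt(cptable[i_sel, "CP"] * cptable[i_sel - 1L, "CP"])
}

.tree_split_features <- function(fit) {
  fr <- fit$frame
  unique(as.character(fr$var[fr$var != "<leaf>"]))
}

#' Fit a cost-complexity pruned classification tree
#'
#' Grows a binary classification tree greedily by Gini gain on the selected
#' features, then prunes it by cost-complexity with the penalty chosen by
#' cross-validated error under the one-standard-error rule. Branches present
#' in the full tree but removed by pruning are recorded in the pruning
#' trace. A table with no valid split yields a single-leaf majority tree.
#'
#' @param tab Patient table.
#' @param selected_features Non-empty character vector of predictor columns.
#' @param label_col Outcome column (default `"label"`).
#' @param params Optional list overriding `minsplit` (20), `cp_grow`
#'   (0.001), `xval` (5), `maxdepth` (30).
#' @param seed Mandatory integer seed (cross-validation randomness).
#' @return An object of class `fitted_tree`: `rpart` (pruned fit), `full`
#'   (unpruned), `selected_features`, `pruned_away` (features whose
#'   branches the pruning removed), `cp`, `params`, `seed`.
#' @export
fit_pruned_tree <- function(tab, selected_features, label_col = "label",
                            params = list(), seed = NULL) {
  if (length(selected_features) == 0L) {
    stop("`selected_features` must be non-empty", call. = FALSE)
  }
  selected_features <- .model_features(tab, selected_features, label_col)
  p <- utils::modifyList(list(minsplit = 20, cp_grow = 0.001, xval = 5,
                              maxdepth = 30), params)
  dat <- tab[, c(selected_features, label_col)]
  dat[[label_col]] <- factor(as.logical(dat[[label_col]]), levels = c(FALSE, TRUE))
  if (length(unique(dat[[label_col]])) < 2L) {
    # degenerate single-class table: a constant-leaf tree, not an error
    return(structure(list(
      rpart = NULL, full = NULL, selected_features = selected_features,
      pruned_away = character(0), cp = Inf, params = p, seed = seed,
      label_col = label_col,
      constant = mean(as.logical(tab[[label_col]]))
    ), class = "fitted_tree"))
  }
  fml <- stats::as.formula(paste(label_col, "~",
                                 paste(selected_features, collapse = " + ")))
  fit <- with_seed(seed, rpart::rpart(
    fml, data = dat, method = "class", parms = list(split = "gini"),
    control = rpart::rpart.control(minsplit = p$minsplit, cp = p$cp_grow,
                                   xval = p$xval, maxdepth = p$maxdepth)))
  cp <- .cp_one_se(fit$cptable)
  pruned <- if (is.finite(cp)) rpart::prune(fit, cp = cp) else
    rpart::prune(fit, cp = fit$cptable[1L, "CP"] + 1)
  structure(list(
    rpart = pruned, full = fit,
    selected_features = selected_features,
    pruned_away = setdiff(.tree_split_features(fit), .tree_split_features(pruned)),
    cp = cp, params = p, seed = seed, label_col = label_col
  ), class = "fitted_tree")
}

#' @export
print.fitted_tree <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<fitted_tree> constant leaf, event probability %.3f\n",
                x$constant))
    return(invisible(x))
  }
  used <- .tree_split_features(x$rpart)
  cat(sprintf("<fitted_tree> %d terminal node(s); splits on: %s\n",
              sum(x$rpart$frame$var == "<leaf>"),
              if (length(used)) paste(used, collapse = ", ") else "(none)"))
  if (length(x$pruned_away)) {
    cat("  pruning removed branch(es) on:", paste(x$pruned_away, collapse = ", "), "\n")
  }
  print(x$rpart)
  invisible(x)
}

#' Predict event probabilities from a fitted tree
#'
#' @param object A [fit_pruned_tree()] result.
#' @param newdata Patient table.
#' @param ... Unused.
#' @return Numeric vector of leaf event probabilities.
#' @export
predict.fitted_tree <- function(object, newdata, ...) {
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(newdata)))
  }
  pr <- predict(object$rpart, newdata = newdata, type = "prob")
  if ("TRUE" %in% colnames(pr)) pr[, "TRUE"] else rep(0, nrow(newdata))
}

.classification_report <- function(label, prob) {
  n <- length(label)
  pred <- prob > 0.5
  tp <- sum(pred & label); tn <- sum(!pred & !label)
  fp <- sum(pred & !label); fn <- sum(!pred & label)
  accuracy <- (tp + tn) / n
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  n1 <- sum(label); n0 <- n - n1
  auroc <- if (n1 == 0L || n0 == 0L) NA_real_ else {
    r <- rank(prob)                       # mid-ranks give the tie-corrected statistic
    (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  nir <- max(n1, n0) / n
  correct <- tp + tn
  nir_p <- pbinom(correct - 1L, n, nir, lower.tail = FALSE)
  structure(list(
    accuracy = accuracy, auroc = auroc, f1 = f1,
    confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                       dimnames = list(predicted = c("FALSE", "TRUE"),
                                       observed = c("FALSE", "TRUE"))),
    nir = nir, nir_p = nir_p, n = n,
    auroc_defined = !(n1 == 0L || n0 == 0L)
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> n = %d | accuracy %.3f | AUROC %s | F1 %s\n",
              x$n, x$accuracy,
              if (is.na(x$auroc)) "undefined" else sprintf("%.3f", x$auroc),
              if (is.na(x$f1)) "undefined" else sprintf("%.3f", x$f1)))
  cat(sprintf("  NIR %.3f, one-sided binomial p = %.4g\n", x$nir, x$nir_p))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted tree
#'
#' Two schemes are available. `"holdout"` scores the supplied tree on
#' `tab` as an external set. `"cv-pooled"` treats the tree as a recipe: its
#' selected features and control parameters are refitted on the training
#' part of each stratified fold and the out-of-fold leaf probabilities are
#' pooled before computing the metrics, so every patient is scored by a
#' tree that never saw them. Accuracy, F1 (positive class = event) and the
#' confusion matrix use the 0.5 probability cut; AUROC uses the
#' tie-corrected rank statistic on the leaf probabilities; the
#' no-information rate (majority-class frequency) is tested against the
#' observed accuracy with a one-sided exact binomial tail.
#'
#' @param tree A [fit_pruned_tree()] result.
#' @param tab Patient table to evaluate on.
#' @param scheme `"cv-pooled"` (default) or `"holdout"`.
#' @param k_folds Folds for `"cv-pooled"` (default 5).
#' @param seed Mandatory for `"cv-pooled"`.
#' @return A list of class `model_report`: `accuracy`, `auroc`, `f1`,
#'   `confusion` (2x2), `nir`, `nir_p`, `n`. AUROC is `NA` (flagged via
#'   `auroc_defined`) when only one class is present.
#' @export
evaluate_model <- function(tree, tab, scheme = c("cv-pooled", "holdout"),
                           k_folds = 5, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!inherits(tree, "fitted_tree")) stop("`tree` must be a fitted_tree", call. = FALSE)
  label <- as.logical(tab[[tree$label_col]])
  if (scheme == "holdout") {
    prob <- predict(tree, tab)
  } else {
    prob <- rep(NA_real_, nrow(tab))
    with_seed(seed, {
      fold <- .stratified_folds(label, k_folds)
      for (f in seq_len(k_folds)) {
        tr <- fold != f
        sub_tree <- fit_pruned_tree(tab[tr, , drop = FALSE],
                                    tree$selected_features,
                                    label_col = tree$label_col,
                                    params = tree$params,
                                    seed = child_seed(seed, f))
        prob[!tr] <- predict(sub_tree, tab[!tr, , drop = FALSE])
      }
    })
  }
  .classification_report(label, prob)
}

#' Run the full risk-modeling pipeline on a cohort
#'
#' End to end, per treatment group when a group column is present:
#' random-forest feature ranking, pruned-tree fitting on the top-k
#' features, cross-validated (or held-out) evaluation, and — when paired
#' `<metric>_pre`/`<metric>_post` columns exist — the pre/post biomarker
#' comparison report. Every stage derives its seed from `config$seed`, so
#' two runs with the same config are identical.
#'
#' @param cohort Patient table.
#' @param config List: `seed` (mandatory), and optionally `features`,
#'   `label_col` ("label"), `group_col`, `top_k` (3), `ntree` (500),
#'   `k_folds` (5), `scheme` ("cv-pooled"), `tree_params` (list).
#' @return A list of class `pipeline_result`, one element per group, each
#'   with `ranking`, `tree`, `report`, and `comparison` (or `NULL`);
#'   plus the `config` used.
#' @export
run_pipeline <- function(cohort, config = list()) {
  if (is.null(config$seed)) {
    stop("`config$seed` is mandatory: every stochastic stage is seeded from it",
         call. = FALSE)
  }
  cfg <- utils::modifyList(list(features = NULL, label_col = "label",
                                group_col = NULL, top_k = 3, ntree = 500,
                                k_folds = 5, scheme = "cv-pooled",
                                tree_params = list()), config)
  groups <- if (is.null(cfg$group_col)) list(all = cohort) else
    split(cohort, cohort[[cfg$group_col]])
  out <- list()
  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]
    sub <- groups[[gi]]
    ranking <- rank_features(sub, features = cfg$features,
                             label_col = cfg$label_col, k_folds = cfg$k_folds,
                             ntree = cfg$ntree, top_k = cfg$top_k,
                             seed = child_seed(cfg$seed, 10L + gi))
    tree <- fit_pruned_tree(sub, attr(ranking, "top"),
                            label_col = cfg$label_col, params = cfg$tree_params,
                            seed = child_seed(cfg$seed, 20L + gi))
    report <- evaluate_model(tree, sub, scheme = cfg$scheme,
                             k_folds = cfg$k_folds,
                             seed = child_seed(cfg$seed, 30L + gi))
    comparison <- NULL
    if (all(c("boxfd_pre", "boxfd_post") %in% names(sub))) {
      comparison <- compare_pre_post(sub)
    }
    out[[g]] <- list(ranking = ranking, tree = tree, report = report,
                     comparison = comparison)
  }
  structure(list(groups = out, config = cfg), class = "pipeline_result")
}
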