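planted_v20_cohort <- function(seed, n = 166, noise = 2, label_noise = 0) {
  generate_cohort(cohort_spec(
    n, tree_rules = list(list(feature = "v20_pct", threshold = 17.5, p_gt = 1)),
    p_else = 0, noise_features = noise, label_noise = label_noise, seed = seed))
}

test_that("the planted driver dominates the Gini importance ranking", {
  wins <- 0L
  for (seed in 1:20) {
    co <- planted_v20_cohort(seed)
    rk <- rank_features(co, seed = 300 + seed, ntree = 200)
    noise_imp <- rk$importance[grepl("^noise_", rk$feature)]
    ok <- rk$feature[1] == "v20_pct" &&
      rk$importance[rk$feature == "v20_pct"] >= 5 * median(noise_imp)
    wins <- wins + ok
  }
  expect_gte(wins, 19)
})

test_that("pure-noise labels produce no dominant feature", {
  flat <- 0L
  for (seed in 1:10) {
    set.seed(seed + 400)
    co <- data.frame(matrix(runif(120 * 8), ncol = 8))
    names(co) <- paste0("f", 1:8)
    co$label <- rep(c(TRUE, FALSE), 60)
    rk <- rank_features(co, seed = 500 + seed, ntree = 200)
    flat <- flat + all(rk$importance <= 3 * median(rk$importance))
  }
  expect_gte(flat, 9)
})

test_that("rankings are deterministic for a fixed seed and reject degenerate labels", {
  co <- planted_v20_cohort(7)
  a <- rank_features(co, seed = 11, ntree = 100)
  b <- rank_features(co, seed = 11, ntree = 100)
  expect_identical(a$importance, b$importance)
  co$label <- TRUE
  expect_error(rank_features(co, seed = 11), "single class")
  expect_error(rank_features(co[1:10, ], seed = 11), "at least 20 rows")
})

test_that("a one-threshold cohort yields a depth-1 tree with the threshold in the gap", {
  co <- planted_v20_cohort(3)
  tr <- fit_pruned_tree(co, "v20_pct", seed = 4)
  fr <- tr$rpart$frame
  expect_equal(sum(fr$var == "<leaf>"), 2)
  cut <- tr$rpart$splits[1, "index"]
  below <- max(co$v20_pct[co$v20_pct <= 17.5])
  above <- min(co$v20_pct[co$v20_pct > 17.5])
  expect_gt(cut, below)
  expect_lt(cut, above)
})

test_that("pruning removes noise-feature branches in planted two-rule cohorts", {
  clean <- 0L
  for (seed in 1:10) {
    co <- generate_cohort(cohort_spec(
      166, tree_rules = list(
        list(feature = "v20_pct", threshold = 17.5, p_gt = 1),
        list(feature = "d_lacunarity", threshold = 0.02, p_gt = 1)),
      p_else = 0, noise_features = 1, seed = 600 + seed))
    tr <- fit_pruned_tree(co, c("v20_pct", "d_lacunarity", "noise_1"),
                          seed = 700 + seed)
    used <- unique(as.character(tr$rpart$frame$var))
    clean <- clean + !("noise_1" %in% used)
  }
  expect_gte(clean, 9)
})

test_that("single-class input collapses to a single pure leaf", {
  co <- planted_v20_cohort(5)
  co$label <- FALSE
  co$rp_grade <- 0L
  tr <- fit_pruned_tree(co, "v20_pct", seed = 6)
  expect_equal(unique(predict(tr, co)), 0)
})

test_that("evaluation metrics are exact on constructed predictions", {
  co <- planted_v20_cohort(8)
  tr <- fit_pruned_tree(co, "v20_pct", seed = 9)
  rep <- evaluate_model(tr, co, scheme = "holdout")
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$f1, 1)
  expect_equal(rep$auroc, 1)
  expect_equal(sum(rep$confusion), nrow(co))

  # majority-vote predictor: tree trained on single-class data
  maj <- fit_pruned_tree(transform(co, label = FALSE), "v20_pct", seed = 10)
  rep0 <- evaluate_model(maj, co, scheme = "holdout")
  expect_equal(rep0$accuracy, rep0$nir)
  expect_gte(rep0$nir_p, 0.5)
})

test_that("AUROC equals the brute-force pairwise oracle including ties", {
  set.seed(123)
  for (i in 1:5) {
    n <- 60
    label <- runif(n) < 0.4
    score <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    co <- data.frame(x = score, label = label)
    # score the labels directly through the internal report
    rep <- lungfractal:::.classification_report(label, score)
    expect_equal(rep$auroc, oracle_auroc(label, score), tolerance = 1e-9)
  }
})

test_that("the NIR binomial tail matches exact summation", {
  # balanced labels (NIR 0.5), 60 of 100 predictions correct
  label <- c(rep(TRUE, 50), rep(FALSE, 50))
  prob <- c(rep(1, 30), rep(0, 20), rep(1, 20), rep(0, 30))
  rep <- lungfractal:::.classification_report(label, prob)
  expect_equal(rep$accuracy, 0.6)
  expect_equal(rep$nir, 0.5)
  expect_equal(rep$nir_p, oracle_binom_tail(60, 100, 0.5), tolerance = 1e-12)
  expect_equal(round(rep$nir_p, 5), 0.02844)
})

test_that("the full pipeline is deterministic and recovers planted structure", {
  co <- planted_v20_cohort(21)
  cfg <- list(seed = 31, ntree = 200)
  a <- run_pipeline(co, cfg)
  b <- run_pipeline(co, cfg)
  expect_identical(serialize(a$groups$all$report, NULL),
                   serialize(b$groups$all$report, NULL))
  expect_gte(a$groups$all$report$accuracy, 0.95)
  expect_true("v20_pct" %in% attr(a$groups$all$ranking, "top"))
  expect_error(run_pipeline(co, list()), "seed")
})

test_that("noisy labels still beat the no-information rate in pooled CV", {
  better <- 0L
  for (seed in 1:10) {
    co <- planted_v20_cohort(800 + seed, label_noise = 0.2)
    if (length(unique(co$label)) < 2) next
    res <- run_pipeline(co, list(seed = 900 + seed, ntree = 100,
                                 features = c("v20_pct", "mld_cgy", "age")))
    rep <- res$groups$all$report
    better <- better + (rep$accuracy > rep$nir)
  }
  expect_gte(better, 8)
})
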