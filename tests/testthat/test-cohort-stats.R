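test_that("event-rate percentages follow exact arithmetic under each rounding mode", {
  expect_equal(percent_value(19 / 85), 22.4)               # 22.3529... half-up
  expect_equal(percent_value(19 / 85, mode = "truncate"), 22.3)
  expect_equal(percent_value(44 / 81), 54.3)
  expect_equal(percent_value(6 / 85), 7.1)
  expect_equal(percent_value(16 / 81), 19.8)
  expect_equal(percent_value(0 / 50), 0)
  expect_equal(percent_value(0.225), 22.5)
  expect_equal(percent_value(0.225, mode = "half-down"), 22.5 - 0.1 + 0.1) # exact .5 stays
})

test_that("cohort summaries carry counts, percentages and medians per group", {
  set.seed(101)
  tab <- data.frame(
    patient_id = sprintf("P%03d", 1:60),
    group = rep(c("RT", "CCRT"), each = 30),
    sex = sample(c("F", "M"), 60, replace = TRUE),
    age = sample(40:90, 60, replace = TRUE),
    rp_grade = c(rep(0, 22), rep(2, 6), rep(3, 2), rep(0, 14), rep(2, 10),
                 rep(3, 6))
  )
  s <- summarize_cohort(tab, group_col = "group")
  rt2 <- s[s$group == "RT" & s$characteristic == "rp_grade_ge2", ]
  expect_equal(rt2$n, 8)
  expect_equal(rt2$percent, percent_value(8 / 30))
  cc3 <- s[s$group == "CCRT" & s$characteristic == "rp_grade_ge3", ]
  expect_equal(cc3$n, 6)
  age_rt <- s[s$group == "RT" & s$characteristic == "age", ]
  expect_equal(age_rt$median, median(tab$age[tab$group == "RT"]))
  # exclusive categorical levels sum to 100 up to rounding
  sex_rt <- s[s$group == "RT" & s$characteristic == "sex", ]
  expect_equal(sum(sex_rt$percent), 100, tolerance = 0.11)
  expect_error(summarize_cohort(tab[, -5]), "rp_grade")
})

test_that("paired comparison flags the planted lacunarity shift and only it", {
  tab <- generate_paired_cohort(60, seed = 5)
  rep <- compare_pre_post(tab, alternative = "greater")
  expect_lt(rep$p_value[rep$metric == "lacunarity"], 0.05)
  expect_gt(rep$p_value[rep$metric == "boxfd"], 0.05)
  expect_gt(rep$p_value[rep$metric == "mstfd"], 0.05)
  expect_gt(rep$diff_median[rep$metric == "lacunarity"], 0)
  expect_true(all(rep$diff_q1 <= rep$diff_median & rep$diff_median <= rep$diff_q3))
})

test_that("a single-patient cohort degenerates to its own values", {
  tab <- data.frame(boxfd_pre = 2.3, boxfd_post = 2.28,
                    lacunarity_pre = 0.14, lacunarity_post = 0.15,
                    mstfd_pre = 2.73, mstfd_post = 2.72)
  rep <- compare_pre_post(tab)
  expect_equal(rep$pre_median[rep$metric == "boxfd"], 2.3)
  expect_equal(rep$pre_q1[rep$metric == "boxfd"], 2.3)
  expect_equal(rep$diff_median[rep$metric == "lacunarity"], 0.01)
})

test_that("unpaired patients are listed by identifier", {
  tab <- generate_paired_cohort(5, seed = 6)
  tab$lacunarity_post[3] <- NA
  expect_error(compare_pre_post(tab), "P0003")
})

test_that("under a global null the comparison keeps its nominal type-I error", {
  hits <- 0L
  n_rep <- 400L
  for (r in seq_len(n_rep)) {
    tab <- generate_paired_cohort(50,
                                  shifts = c(boxfd = 0, lacunarity = 0,
                                             mstfd = 0),
                                  seed = 5000 + r)
    p <- compare_pre_post(tab, metrics = "lacunarity")$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / n_rep, 0.02)
  expect_lt(hits / n_rep, 0.09)
})
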