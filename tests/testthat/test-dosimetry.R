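test_that("uniform and two-level dose fields give textbook DVH values", {
  lung <- binary_mask(array(TRUE, dim = c(4, 4, 4)))
  u <- dvh_metrics(array(10, dim = c(4, 4, 4)), lung)
  expect_equal(u$v5_pct, 100)
  expect_equal(u$v10_pct, 100)  # inclusive threshold: 10 Gy counts for V10
  expect_equal(u$v20_pct, 0)
  expect_equal(u$mld_cgy, 1000)

  dose <- array(0, dim = c(4, 4, 4))
  dose[1:2, , ] <- 30
  h <- dvh_metrics(dose, lung)
  expect_equal(h$v20_pct, 50)
  expect_equal(h$mld_cgy, 1500)
})

test_that("DVH metrics equal a voxel-by-voxel brute-force scan on random grids", {
  set.seed(55)
  dose <- array(runif(6 * 5 * 4, 0, 40), dim = c(6, 5, 4))
  lung <- random_mask(c(6, 5, 4), p = 0.6, seed = 5)
  got <- dvh_metrics(dose, lung)
  tot <- 0; n <- 0; c5 <- 0; c10 <- 0; c20 <- 0
  for (i in 1:6) for (j in 1:5) for (k in 1:4) {
    if (lung$occupancy[i, j, k]) {
      n <- n + 1; tot <- tot + dose[i, j, k]
      c5 <- c5 + (dose[i, j, k] >= 5)
      c10 <- c10 + (dose[i, j, k] >= 10)
      c20 <- c20 + (dose[i, j, k] >= 20)
    }
  }
  expect_equal(got$mld_cgy, 100 * tot / n)
  expect_equal(got$v5_pct, 100 * c5 / n)
  expect_equal(got$v10_pct, 100 * c10 / n)
  expect_equal(got$v20_pct, 100 * c20 / n)
})

test_that("Vx is monotone in x and scales coherently with dose", {
  lung <- binary_mask(array(TRUE, dim = c(5, 5, 5)))
  for (seed in 1:3) {
    set.seed(seed)
    dose <- array(runif(125, 0, 30), dim = c(5, 5, 5))
    m <- dvh_metrics(dose, lung)
    expect_true(m$v5_pct >= m$v10_pct && m$v10_pct >= m$v20_pct)
    m2 <- dvh_metrics(dose * 2, lung)
    expect_equal(m2$mld_cgy, 2 * m$mld_cgy)
    expect_equal(m2$v10_pct, m$v5_pct)  # doubling dose shifts thresholds
  }
})

test_that("DVH tables are validated on read", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(patient_id = "P1", mld_cgy = 423, v5_pct = 20.0,
                       v10_pct = 11.0, v20_pct = 5.9),
            f, row.names = FALSE)
  tab <- read_dvh_table(f)
  expect_equal(tab$mld_cgy, 423)
  expect_equal(tab$v20_pct, 5.9)

  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(mld_cgy = 400, v5_pct = 5, v10_pct = 4, v20_pct = 6),
            f2, row.names = FALSE)
  expect_warning(tab2 <- read_dvh_table(f2), "V5 >= V10 >= V20")
  expect_equal(nrow(tab2), 1)

  f3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(mld_cgy = 400, v5_pct = 50, v10_pct = 40,
                       v20_pct = 363.0),
            f3, row.names = FALSE)
  expect_error(read_dvh_table(f3), "outside \\[0, 100\\]")

  f4 <- tempfile(fileext = ".csv")
  write.csv(data.frame(mld_cgy = numeric(0), v5_pct = numeric(0),
                       v10_pct = numeric(0), v20_pct = numeric(0)),
            f4, row.names = FALSE)
  expect_error(read_dvh_table(f4), "empty")

  f5 <- tempfile(fileext = ".csv")
  write.csv(data.frame(mld_cgy = 400), f5, row.names = FALSE)
  expect_error(read_dvh_table(f5), "mandatory column")
})

test_that("geometry and emptiness errors are raised", {
  lung <- binary_mask(array(TRUE, dim = c(4, 4, 4)))
  expect_error(dvh_metrics(array(1, dim = c(3, 4, 4)), lung), "geometry")
  empty <- binary_mask(array(FALSE, dim = c(4, 4, 4)))
  expect_error(dvh_metrics(array(1, dim = c(4, 4, 4)), empty), "empty")
  expect_error(dvh_metrics(array(-1, dim = c(4, 4, 4)), lung), "non-negative")
})
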