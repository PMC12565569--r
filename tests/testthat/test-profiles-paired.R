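settings_small <- function(seed = 1) {
  fractal_settings(mst_sizes = c(32, 64, 128), mst_reps = 5, seed = seed)
}

test_that("identical pre/post masks give an all-zero delta profile", {
  m <- generate_phantom(phantom_spec("thresholded_field", size = 24,
                                     occupancy = 0.4, correlation_length = 2,
                                     seed = 9))
  pp <- compute_profile(m, m, settings_small())
  expect_identical(pp$delta$d_boxfd, 0)
  expect_identical(pp$delta$d_lacunarity, 0)
  expect_identical(pp$delta$d_mstfd, 0)
})

test_that("delta components equal post minus pre exactly", {
  pre <- generate_phantom(phantom_spec("thresholded_field", size = 24,
                                       occupancy = 0.4, correlation_length = 2,
                                       seed = 10))
  post <- generate_phantom(phantom_spec("thresholded_field", size = 24,
                                        occupancy = 0.4, correlation_length = 3,
                                        seed = 11))
  pp <- compute_profile(pre, post, settings_small())
  expect_identical(pp$delta$d_boxfd, pp$post$boxfd - pp$pre$boxfd)
  expect_identical(pp$delta$d_lacunarity, pp$post$lacunarity - pp$pre$lacunarity)
  expect_identical(pp$delta$d_mstfd, pp$post$mstfd - pp$pre$mstfd)
})

test_that("profiles record settings and seed in their diagnostics", {
  m <- generate_phantom(phantom_spec("thresholded_field", size = 24,
                                     occupancy = 0.4, correlation_length = 2,
                                     seed = 12))
  pr <- fractal_profile(m, settings_small(seed = 77))
  expect_identical(pr$diagnostics$settings$seed, 77L)
  expect_false(pr$diagnostics$mst_flagged)
  expect_s3_class(pr$diagnostics$box_curve, "data.frame")
})

test_that("lung-texture phantoms land in plausible biomarker ranges", {
  m <- generate_phantom(phantom_spec("thresholded_field", size = 48,
                                     occupancy = 0.55, correlation_length = 1.5,
                                     seed = 13))
  pr <- fractal_profile(m, fractal_settings(mst_sizes = c(128, 256, 512, 1024),
                                            mst_reps = 5, seed = 14))
  expect_gt(pr$boxfd, 2.0); expect_lt(pr$boxfd, 3.0)
  expect_gt(pr$lacunarity, 0.01); expect_lt(pr$lacunarity, 1)
  expect_gt(pr$mstfd, 2.4); expect_lte(pr$mstfd, 3.1)
})

test_that("planted paired volumes realize the contracted effect", {
  base <- phantom_spec("thresholded_field", size = 32, occupancy = 0.4,
                       correlation_length = 2, seed = 21)
  spec <- paired_effect_spec(base, lacunarity_shift = 0.35,
                             preserve_boxfd_tol = 0.05)
  pv <- generate_paired_volumes(spec)
  d_lac <- lacunarity(pv$post)$estimate - lacunarity(pv$pre)$estimate
  d_box <- box_counting_dimension(pv$post)$estimate -
    box_counting_dimension(pv$pre)$estimate
  expect_gt(d_lac, 0)
  expect_lte(abs(d_box), 0.05)

  neg <- generate_paired_volumes(paired_effect_spec(base, -0.35))
  expect_lt(lacunarity(neg$post)$estimate - lacunarity(neg$pre)$estimate, 0)

  same <- generate_paired_volumes(paired_effect_spec(base, 0))
  expect_identical(same$pre, same$post)
})

test_that("unachievable paired effects fail with the violated constraint named", {
  base <- phantom_spec("thresholded_field", size = 16, occupancy = 0.5,
                       correlation_length = 2, seed = 22)
  spec <- paired_effect_spec(base, lacunarity_shift = 0.9,
                             preserve_boxfd_tol = 1e-6, max_tries = 3)
  expect_error(generate_paired_volumes(spec),
               "failed after 3 attempts.*(BoxFD not preserved|sign not realized)")
})

test_that("degenerate masks are rejected before any metric runs", {
  occ <- array(FALSE, dim = c(8, 8, 8)); occ[1] <- TRUE
  expect_error(fractal_profile(binary_mask(occ), settings_small()),
               "fewer than 2 occupied voxels")
})
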