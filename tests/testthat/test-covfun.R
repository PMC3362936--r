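test_that("the covariance function reproduces worked trajectory values", {
  g <- table1_g_block()
  expect_equal(trajectory_variance(g, 0), 10640)
  # independent arithmetic oracle for the quadratic form at t = 17.5
  t <- 17.5
  oracle <- 10640 + 2 * t * (-0.30 * sqrt(10640 * 57.8)) + t^2 * 57.8
  expect_equal(trajectory_variance(g, t), oracle)
  expect_equal(oracle, 20107.5, tolerance = 1e-4)

  flat <- gencov2(10640, 0, 0)
  expect_equal(trajectory_variance(flat, c(0, 5, 20)), rep(10640, 3))
  expect_error(trajectory_variance(g, -1), "non-negative")
})

test_that("variance ratios match the printed component arithmetic", {
  r <- variance_ratios(309, 59.3, 577.7)
  expect_equal(r$v_p, 946)
  expect_equal(round(r$h2, 2), 0.33)
  expect_equal(round(r$m2, 2), 0.06)
  r2 <- variance_ratios(12952, 2913, 57614)
  expect_equal(round(r2$h2, 2), 0.18)
  expect_equal(round(r2$m2, 2), 0.04)
  expect_error(variance_ratios(0, 0, 0), "positive")
})

test_that("correlation with the healthy point behaves like a correlation", {
  g <- table1_g_block()
  expect_identical(correlation_with_healthy(g, 0), 1)
  expect_equal(round(correlation_with_healthy(g, 17.5), 2), 0.45)

  # closed form when the covariance is zero: v0 / sqrt(v0 (v0 + t^2 v1))
  g0 <- gencov2(100, 4, 0)
  t <- c(0, 1, 3, 10)
  expect_equal(correlation_with_healthy(g0, t),
               100 / sqrt(100 * (100 + t^2 * 4)))
  r <- correlation_with_healthy(g0, seq(0, 30, 0.5))
  expect_true(all(diff(r) < 0))
  expect_true(all(r > 0))

  # bounded by 1 and decreasing under negative covariance, random PSD blocks
  set.seed(9)
  for (i in 1:25) {
    v0 <- stats::runif(1, 1, 1e4)
    v1 <- stats::runif(1, 0.1, 100)
    rho <- stats::runif(1, -0.95, 0.95)
    g <- gencov2(v0, v1, rho * sqrt(v0 * v1))
    tt <- seq(0, 25, by = 0.5)
    r <- correlation_with_healthy(g, tt)
    expect_true(all(abs(r) <= 1 + 1e-12))
    expect_true(all(trajectory_variance(g, tt) >= -1e-9))
    if (rho < 0) expect_true(all(diff(r) < 1e-12))
  }
  expect_error(correlation_with_healthy(gencov2(0, 1, 0), 1), "positive")
})

test_that("trajectory summaries satisfy the component identity", {
  g_toy <- gencov2(1, 0, 0)
  ts <- trajectory_ratios(g_toy, g_toy, rep(1, 5), grid = 0)
  expect_equal(ts$trajectory$h2, 1 / 3)
  expect_equal(ts$trajectory$m2, 1 / 3)

  g_gen <- table1_g_block()
  g_mat <- gencov2(2771, 23.0, -0.26 * sqrt(2771 * 23.0))
  ve <- c(43800, 44750, 60500, 64700, 93800)
  ts <- trajectory_ratios(g_gen, g_mat, ve,
                          class_means = 2080 - 14.6 * c(0, 2.5, 7.5, 12.5, 17.5))
  tr <- ts$trajectory
  expect_equal(tr$v_p, tr$v_g + tr$v_m + tr$v_e)  # identity by construction
  expect_true(all(tr$h2 >= 0 & tr$h2 <= 1))
  expect_true(all(tr$m2 >= 0 & tr$m2 <= 1))
  expect_equal(tr$r_with_healthy[tr$ratioplat == 0], 1)
  expect_equal(tr$heart_ratio, tr$ratioplat + 29)
  # per-class CV is increasing under the calibrated defaults
  expect_true(all(diff(ts$cv$cv) > 0))
  expect_error(trajectory_ratios(g_gen, g_mat, ve[1:3]), "per severity class")
})
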