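test_that("simulation is deterministic given config and seed", {
  cfg <- sim_preset("small")
  a <- simulate_population(cfg, 42)
  b <- simulate_population(cfg, 42)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$truth$additive, b$truth$additive)
  c <- simulate_population(cfg, 43)
  expect_false(identical(a$phenotypes$bw7, c$phenotypes$bw7))
})

test_that("the mating design matches the configured structure", {
  cfg <- sim_config()  # full study design
  pi <- simulate_pedigree(cfg, 5)
  expect_equal(length(unique(pi$meta$sire)), 83)
  expect_equal(nrow(pi$meta), 7722)
  off <- pi$pedigree[!is.na(pi$pedigree$sire), ]
  expect_true(all(!is.na(off$dam)))

  # mean dams per sire close to the configured 15.7 across seeds
  dps <- vapply(1:15, function(s) {
    m <- simulate_pedigree(cfg, 100 + s)$meta
    mean(tapply(m$dam, m$sire, function(x) length(unique(x))))
  }, numeric(1))
  expect_lt(abs(mean(dps) - 788 * 1.65 / 83) / (788 * 1.65 / 83), 0.05)

  expect_error(simulate_pedigree(sim_config(n_sires = 0), 1), "n_sires")
})

test_that("founder values reproduce the 4x4 covariance structure", {
  cfg <- sim_config(nested = TRUE, n_sires = 10000, dams_per_sire = 1,
                    offspring_per_dam = 1)
  pi <- simulate_pedigree(cfg, 3)
  gv <- simulate_genetic_values(pi$pedigree, cfg, 4)
  founders <- is.na(pi$pedigree$sire)
  cc <- stats::cov(gv$additive[founders, ])
  scale <- sqrt(diag(gv$sigma_g) %o% diag(gv$sigma_g))
  expect_lt(max(abs(cc - gv$sigma_g) / scale), 0.05)

  # parent-offspring covariance of slope values is half the slope variance
  off <- pi$pedigree$animal[!founders]
  po <- stats::cov(gv$additive[off, "slope"],
                   gv$additive[pi$pedigree$sire[!founders], "slope"])
  expect_lt(abs(po - 57.8 / 2) / (57.8 / 2), 0.15)
})

test_that("a zero-variance configuration produces zero genetic values", {
  cfg <- sim_config(nested = TRUE, n_sires = 5, dams_per_sire = 2,
                    offspring_per_dam = 3,
                    genetic_vars = c(bw2 = 0, ratio = 0, intercept = 0, slope = 0),
                    maternal_vars = c(bw2 = 0, ratio = 0, intercept = 0, slope = 0))
  pi <- simulate_pedigree(cfg, 1)
  gv <- simulate_genetic_values(pi$pedigree, cfg, 2)
  expect_true(all(gv$additive == 0))
  expect_true(all(gv$maternal == 0))
})

test_that("the affected fraction matches the closed-form normal tail", {
  cfg <- sim_config()  # 7722 offspring
  pop <- simulate_population(cfg, 11)
  ratio <- pop$phenotypes$ratio
  frac <- mean(ratio > cfg$threshold, na.rm = TRUE)
  # total RATIO variance 15.1 + 1.17 + 30.45 = 46.72 around mean 28.2;
  # allow for the small centered fixed-effect variance on top
  p0 <- 1 - stats::pnorm((29 - 28.2) / sqrt(46.72))
  n <- sum(!is.na(ratio))
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n) + 0.005)
})

test_that("record losses and class variance heterogeneity match the design", {
  cfg <- sim_preset("small")
  fr7 <- vapply(1:6, function(s) {
    mean(is.na(simulate_population(cfg, 200 + s)$phenotypes$bw7))
  }, numeric(1))
  expect_lt(abs(mean(fr7) - 0.09), 0.01)

  pop <- simulate_population(sim_config(), 21)
  ph <- pop$phenotypes
  ok <- !is.na(ph$ratio) & !is.na(ph$bw7)
  cls <- residual_class(code_ratioplat(ph$ratio[ok]))
  cv <- vapply(1:5, function(cc) {
    y <- ph$bw7[ok][cls == cc]
    100 * stats::sd(y) / mean(y)
  }, numeric(1))
  # phenotypic CV rises along the severity classes under the calibrated
  # residual defaults (healthy pair of classes roughly flat)
  expect_gt(cv[5], cv[1])
  expect_gt(cv[4], cv[2])
  expect_gt(cv[3], cv[2])
  expect_true(all(cv > 8 & cv < 25))
})

test_that("slope-free generation decouples 7-week weight from severity", {
  cfg <- sim_config(nested = TRUE, n_sires = 30, dams_per_sire = 6,
                    offspring_per_dam = 8,
                    genetic_vars = c(bw2 = 309, ratio = 15.1, intercept = 10640, slope = 0),
                    maternal_vars = c(bw2 = 59.3, ratio = 1.17, intercept = 2771, slope = 0),
                    genetic_corr = diag(4), maternal_corr = diag(4),
                    population_slope = 0,
                    slope_batchstable = rep(0, 10), slope_cutter = rep(0, 11))
  pop <- simulate_population(cfg, 31)
  ph <- pop$phenotypes
  ok <- !is.na(ph$ratio) & !is.na(ph$bw7)
  t <- code_ratioplat(ph$ratio[ok])
  r <- stats::cor(t[t > 0], ph$bw7[ok][t > 0])
  expect_lt(abs(r), 0.1)
})
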