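test_that("pre-canned model specifications have the documented shape", {
  m1 <- model1_spec("bw2")
  expect_equal(m1$fixed_terms, c("gender", "batch_stable", "age"))
  expect_length(m1$random, 2)
  expect_equal(m1$residual, "homogeneous")

  m1b <- model1_spec("bw7")
  expect_equal(m1b$response, "bw7")
  expect_equal(m1b$fixed_terms, m1$fixed_terms)

  m2 <- model2_spec()
  expect_equal(length(m2$fixed_terms), 4)
  expect_true("person" %in% m2$fixed_terms)

  m3 <- model3_spec()
  expect_true("slope_terms" %in% m3$fixed_terms)
  expect_equal(m3$random[[1]]$design, "reaction_norm")
  expect_error(model_spec("bw5"))
})

test_that("the tolerance model has 11 variance parameters (3+3+5)", {
  fit <- fit3_small(1)
  expect_equal(fit$n_parameters, 11)
  expect_equal(sum(grepl("^residual\\.class", names(fit$components))), 5)

  # the BW2 covariate adds a fixed column, not a variance parameter
  pop <- pop_small(1)
  d0 <- build_design(model3_spec(), pop$phenotypes, pop$pedigree)
  d1 <- build_design(model3_spec(include_bw2_covariate = TRUE),
                     pop$phenotypes, pop$pedigree)
  expect_equal(ncol(d1$X), ncol(d0$X) + 1)
})

test_that("omitting the cutter effect inflates the residual variance", {
  cfg <- sim_preset("small", cutter_ratio = seq(-2.5, 2.5, length.out = 11))
  pop <- simulate_population(cfg, 71)
  with_person <- reml_fit(model2_spec(), pop$phenotypes, pop$pedigree,
                          se = "none")
  no_person <- model_spec("ratio",
                          fixed_terms = c("gender", "batch_stable", "age"),
                          residual = "homogeneous")
  without <- reml_fit(no_person, pop$phenotypes, pop$pedigree, se = "none")
  expect_gt(without$components[["residual.var"]],
            with_person$components[["residual.var"]] + 0.5)
})

test_that("healthy-only genetic variance matches the reaction-norm intercept", {
  pop <- pop_small(1)
  fit3 <- fit3_small(1)
  ph <- pop$phenotypes
  healthy <- ph[!is.na(ph$ratio) & ph$ratio <= 29, ]
  healthy <- as_phenotypes(as.data.frame(healthy))
  fit_h <- reml_fit(model1_spec("bw7"), healthy, pop$pedigree, se = "none")
  vi <- fit3$components[["animal.var_intercept"]]
  vh <- fit_h$components[["animal.var"]]
  # same order of magnitude (the study reports 10640 vs 12952)
  expect_gt(vi / vh, 0.4)
  expect_lt(vi / vh, 2.5)
})

test_that("removing slope effects collapses the fitted slope variance", {
  cfg <- sim_preset("small",
                    genetic_vars = c(bw2 = 309, ratio = 15.1,
                                     intercept = 10640, slope = 0.01),
                    maternal_vars = c(bw2 = 59.3, ratio = 1.17,
                                      intercept = 2771, slope = 0.01),
                    genetic_corr = diag(4), maternal_corr = diag(4))
  pop <- simulate_population(cfg, 81)
  fit <- reml_fit(model3_spec(), pop$phenotypes, pop$pedigree, se = "none")
  full <- fit3_small(1)
  expect_lt(fit$components[["animal.var_slope"]],
            0.3 * full$components[["animal.var_slope"]])
  sd_null <- stats::sd(fit$ranef$animal[, "slope"])
  sd_full <- stats::sd(full$ranef$animal[, "slope"])
  expect_lt(sd_null, 0.5 * sd_full)
})

test_that("the full analysis bundle assembles every stage", {
  pop <- pop_small(1)
  bundle <- run_full_analysis(pop$phenotypes, pop$pedigree,
                              config = list(se = "none", with_covariate = TRUE))
  expect_s3_class(bundle, "analysis_bundle")
  expect_length(bundle$mean_fits, 3)
  expect_true(all(vapply(bundle$mean_fits, function(f) f$converged, logical(1))))
  expect_true(bundle$tolerance$converged)
  expect_false(is.null(bundle$tolerance_bw2cov))
  expect_s3_class(bundle$trajectories$trajectory, "data.frame")
  expect_equal(bundle$trajectories$trajectory$v_p,
               with(bundle$trajectories$trajectory, v_g + v_m + v_e))
  expect_equal(length(bundle$ebv), 3)
  expect_true(is.data.frame(bundle$significance))

  # the two tolerance fits give slope variances of the same order
  vs0 <- bundle$tolerance$components[["animal.var_slope"]]
  vs1 <- bundle$tolerance_bw2cov$components[["animal.var_slope"]]
  expect_lt(abs(vs0 - vs1), max(60, 0.9 * vs0))

  expect_error(run_full_analysis(pop$phenotypes[0, ], pop$pedigree), "empty")
})
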