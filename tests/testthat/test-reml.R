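test_that("REML equals the ANOVA estimator on a balanced sire design", {
  hs <- halfsib_data(ns = 50, np = 20, vs = 40, ve = 160, seed = 7)
  fit <- reml_fit(mixed_design(hs$y, random = list(
    list(name = "sire", id = hs$sire, structure = "iid"))), se = "hessian")
  oracle <- anova_sire_variance(hs$y, hs$sire, hs$np)
  expect_true(fit$converged)
  expect_lt(abs(fit$components[["sire.var"]] - oracle) / oracle, 1e-6)

  # delta method through the identity returns the component's own SE
  d <- delta_se(fit, function(ph) ph[["sire.var"]])
  expect_true(d$available)
  expect_equal(d$se, fit$se[["sire.var"]], tolerance = 1e-6)
})

test_that("a zero-variance component is driven to the boundary", {
  set.seed(13)
  sire <- rep(paste0("s", 1:40), each = 12)
  y <- 50 + stats::rnorm(480, 0, 4)  # no sire variance at all
  fit <- reml_fit(mixed_design(y, random = list(
    list(name = "sire", id = sire, structure = "iid"))), se = "none")
  # estimate collapses to (sampling noise around) the zero boundary and
  # matches the positive-part ANOVA estimator
  expect_lt(fit$components[["sire.var"]], 0.1 * fit$components[["residual.var"]])
  oracle <- max(anova_sire_variance(y, sire, 12), 0)
  expect_equal(unname(fit$components[["sire.var"]]), oracle, tolerance = 1e-4)
})

test_that("information criteria follow the stated formulas", {
  fake <- list(logL = -10, n_parameters = 2, n_records = 100)
  ic <- information_criteria(fake)
  expect_equal(unname(ic["aic"]), 24)
  expect_equal(unname(ic["bic"]), 2 * 10 + 2 * log(100))

  # a redundant extra parameter cannot raise AIC by more than 2
  hs <- halfsib_data(ns = 25, np = 10, seed = 19)
  f1 <- reml_fit(mixed_design(hs$y, random = list(
    list(name = "sire", id = hs$sire, structure = "iid"))), se = "none")
  split <- rep_len(1:2, length(hs$y))  # arbitrary residual split
  f2 <- reml_fit(mixed_design(hs$y, random = list(
    list(name = "sire", id = hs$sire, structure = "iid")),
    resid_class = split), se = "none")
  expect_gte(f2$logL, f1$logL - 1e-6)
  expect_lte(f2$aic - f1$aic, 2 + 1e-6)
})

test_that("animal-model BLUPs center near zero for base animals", {
  fit <- fit1_small("bw2", 1)
  pop <- pop_small(1)
  founders <- pop$pedigree$animal[is.na(pop$pedigree$sire)]
  ebv <- fit$ranef$animal[founders, 1]
  expect_lt(abs(mean(ebv)), 0.15 * stats::sd(fit$ranef$animal[, 1]))
})

test_that("design construction enforces factor and rank requirements", {
  pop <- pop_small(1)
  ph <- pop$phenotypes
  ph_m <- ph[ph$gender == "m", ]
  expect_error(build_design(model1_spec("bw2"), ph_m, pop$pedigree),
               "single level")

  d <- build_design(model1_spec("bw2"), ph, pop$pedigree)
  expect_equal(d$n, sum(!is.na(ph$bw2)))
  # reference-level coding: intercept + gender(1) + batch x stable (9) + age(1)
  expect_equal(ncol(d$X), 1 + 1 + 9 + 1)

  d3 <- build_design(model3_spec(), ph, pop$pedigree)
  expect_equal(d3$n, sum(!is.na(ph$bw7) & !is.na(ph$ratio)))
  # random-regression term has two columns per animal, slope = severity
  tm <- d3$terms$animal
  expect_equal(tm$k, 2L)
  expect_equal(ncol(tm$Z), 2L * nrow(pop$pedigree))
  rows <- !is.na(ph$bw7) & !is.na(ph$ratio)
  expect_equal(unname(tm$Z[cbind(seq_len(d3$n),
                                 (match(ph$animal[rows], tm$levels) - 1L) * 2L + 2L)]),
               code_ratioplat(ph$ratio[rows]))

  # a bird without 7-week weight is excluded from rows, kept in the pedigree
  expect_lt(d3$n, nrow(ph))
  expect_equal(tm$q, nrow(pop$pedigree))

  # duplicating a column must be reported as confounding
  X <- stats::model.matrix(~ 1, data.frame(x = seq_len(10)))
  X2 <- cbind(X, dup = 1)
  expect_error(mixed_design(stats::rnorm(10), X2, random = list(
    list(name = "g", id = rep(1:2, 5), structure = "iid"))), "rank deficient")
})

test_that("pedigree-structured REML recovers more information than a sire model", {
  # the animal model must reproduce the generating h2 on average; a single
  # replicate check with a generous band (full recovery is in the
  # acceptance suite)
  fit <- fit1_small("bw2", 1)
  comp <- fit$components
  h2 <- comp[["animal.var"]] / sum(comp)
  expect_gt(h2, 0.15)
  expect_lt(h2, 0.55)
  expect_true(fit$converged)
})
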