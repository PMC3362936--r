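# shared fixtures, built in code and cached across test files

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

pop_small <- function(seed = 1) {
  cached(paste0("pop_small_", seed),
         simulate_population(sim_preset("small"), seed))
}

# a compact population for the slower joint fits
pop_tiny <- function(seed = 1) {
  cached(paste0("pop_tiny_", seed),
         simulate_population(sim_config(nested = TRUE, n_sires = 25,
                                        dams_per_sire = 6,
                                        offspring_per_dam = 8), seed))
}

fit3_small <- function(seed = 1) {
  cached(paste0("fit3_small_", seed), {
    pop <- pop_small(seed)
    reml_fit(model3_spec(), pop$phenotypes, pop$pedigree, se = "none")
  })
}

fit1_small <- function(trait = "bw2", seed = 1) {
  cached(paste0("fit1_small_", trait, "_", seed), {
    pop <- pop_small(seed)
    reml_fit(model1_spec(trait), pop$phenotypes, pop$pedigree, se = "none")
  })
}

# random pedigree: nf founders then animals with parents drawn from earlier
random_pedigree <- function(n, nf = 10, seed = 1) {
  set.seed(seed)
  anim <- paste0("a", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    ps <- sample(seq_len(i - 1), 2)
    sire[i] <- anim[ps[1]]
    dam[i] <- anim[ps[2]]
  }
  new_pedigree(anim, sire, dam)
}

# balanced half-sib data for ANOVA-oracle comparisons
halfsib_data <- function(ns = 50, np = 20, vs = 40, ve = 160, seed = 7) {
  set.seed(seed)
  sire <- rep(paste0("s", seq_len(ns)), each = np)
  u <- stats::rnorm(ns, 0, sqrt(vs))[rep(seq_len(ns), each = np)]
  y <- 100 + u + stats::rnorm(ns * np, 0, sqrt(ve))
  list(y = y, sire = sire, ns = ns, np = np)
}

anova_sire_variance <- function(y, sire, np) {
  aov1 <- stats::anova(stats::lm(y ~ sire))
  (aov1["sire", "Mean Sq"] - aov1["Residuals", "Mean Sq"]) / np
}

table1_g_block <- function() {
  gencov2(var_intercept = 10640, var_slope = 57.8,
          cov_intercept_slope = -0.30 * sqrt(10640 * 57.8))
}
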