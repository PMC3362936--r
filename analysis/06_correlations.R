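#!/usr/bin/env Rscript
# Genetic architecture of the defense traits: bivariate fits among the
# trait means (genetic, maternal and phenotypic correlations) and the
# joint trait-by-reaction-norm fits giving correlations of 2-week weight
# and heart ratio with the tolerance intercept and slope (the
# resistance-tolerance trade-off question). These are the slowest fits;
# run them on a reduced simulation if desk time matters.

suppressMessages(library(tolnorm))

ped <- read_pedigree("results/pedigree.csv")
pheno <- read_phenotypes("results/phenotypes.csv", ped)
pheno <- filter_small_sire_families(pheno, 20)

pairs <- list(c("bw2", "bw7"), c("bw2", "ratio"), c("bw7", "ratio"))
rows <- list()
for (pr in pairs) {
  fit <- bivariate_fit(pr[1], pr[2], pheno, ped, se = "hessian")
  r <- bivariate_correlations(fit)
  r$pair <- paste(pr, collapse = "-")
  r$significant <- mapply(function(e, s) {
    if (is.na(s)) NA else correlation_significant(e, s)$significant
  }, r$estimate, r$se)
  rows[[r$pair[1]]] <- r
  cat(sprintf("%s: r_G = %.2f +/- %.2f, r_M = %.2f +/- %.2f, r_P = %.2f\n",
              r$pair[1], r$estimate[1], r$se[1], r$estimate[2], r$se[2],
              r$estimate[3]))
}
write.csv(do.call(rbind, rows), "results/bivariate_correlations.csv",
          row.names = FALSE)

for (trait in c("bw2", "ratio")) {
  fit <- extended_fit(trait, pheno, ped, se = "hessian")
  ce <- fit$components
  r_int <- ce[[paste0("animal.cov_", trait, "_intercept")]] /
    sqrt(ce[[paste0("animal.var_", trait)]] * ce[["animal.var_intercept"]])
  r_slp <- ce[[paste0("animal.cov_", trait, "_slope")]] /
    sqrt(ce[[paste0("animal.var_", trait)]] * ce[["animal.var_slope"]])
  cat(sprintf("%s: r_G with intercept = %.2f, with tolerance slope = %.2f\n",
              trait, r_int, r_slp))
  write_variance_report(fit, "results", paste0("extended_", trait))
}
cat("Wrote results/bivariate_correlations.csv and extended_* reports.\n")
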