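#' Simulation configuration
#'
#' Parameters of the synthetic broiler population generator. Defaults are
#' the study conditions: a sire-dam mating design (83 sires, 788 dams,
#' 7722 offspring across 5 batches x 2 stables), a 4-variate additive
#' genetic and maternal covariance structure over 2-week body weight (BW2),
#' heart ratio (RATIO), healthy-bird 7-week body weight (INTERCEPT) and
#' tolerance slope (SLOPE), a plateau-linear body-weight response to heart
#' ratio with threshold 29 percent, five-class heterogeneous residual
#' variance for 7-week weight, and 9 percent mortality between the two
#' weighings.
#'
#' Class residual variances for 7-week weight are calibrated so that the
#' class-wise phenotypic coefficients of variation follow the increasing
#' sequence 11.5-19.1 percent implied by the variance trajectories and the
#' mean trajectory `2080 - 14.6 t`.
#'
#' Fixed-effect level values (gender, batch x stable, age, cutter, and the
#' fixed slope interactions) are centered constants, small relative to the
#' trait standard deviations, and configurable.
#'
#' @param n_sires,n_dams,n_offspring population design for the
#'   cross-classified (non-nested) mating structure.
#' @param nested logical; if `TRUE` the design is sires x dams-within-sire
#'   x offspring-within-dam with sizes `n_sires`, `dams_per_sire`,
#'   `offspring_per_dam` (each dam mated to a single sire).
#' @param dams_per_sire,offspring_per_dam nested-design sizes.
#' @param sires_per_dam_probs probabilities that a dam is mated to 1, 2 or
#'   3 sires in the cross-classified design (mean 1.65 by default).
#' @param genetic_vars,maternal_vars named additive-genetic and maternal
#'   variances for `bw2`, `ratio`, `intercept`, `slope`.
#' @param genetic_corr,maternal_corr 4x4 correlation matrices over the same
#'   traits (repaired to the nearest positive semidefinite correlation
#'   matrix with a warning if slightly indefinite).
#' @param residual_bw2,residual_ratio residual variances of BW2 and RATIO.
#' @param residual_bw7_classes residual variance of 7-week weight in each
#'   of the five severity classes.
#' @param means trait means: `bw2`, `ratio`, `intercept`.
#' @param population_slope fixed population tolerance slope (g per percent).
#' @param threshold plateau threshold (percent).
#' @param edges residual-class edges (see [residual_class()]).
#' @param mortality probability that a bird dies before the 7-week weighing
#'   (loses both BW7 and RATIO records); applied independently at random.
#' @param ratio_missing additional probability that RATIO alone is missing.
#' @param bw2_missing probability that BW2 is missing.
#' @param n_batches,n_stables,n_cutters factor-level counts.
#' @param gender_bw2,gender_bw7,gender_ratio named gender effects (levels
#'   `m`, `f`).
#' @param batchstable_bw2,batchstable_bw7,batchstable_ratio centered fixed
#'   effects of the batch x stable cells (length `n_batches * n_stables`).
#' @param age_bw2_eff,age_bw7_eff,age_ratio_eff named fixed effects of
#'   recording age (days).
#' @param cutter_ratio centered fixed effects of the heart cutter on RATIO.
#' @param slope_batchstable,slope_cutter centered fixed tolerance-slope
#'   offsets per batch x stable cell and per cutter.
#' @return list of class `sim_config`.
#' @seealso [sim_preset()] for reduced-scale presets.
#' @export
sim_config <- function(
    n_sires = 83, n_dams = 788, n_offspring = 7722, nested = FALSE,
    dams_per_sire = 8, offspring_per_dam = 10,
    sires_per_dam_probs = c(0.45, 0.45, 0.10),
    genetic_vars = c(bw2 = 309, ratio = 15.1, intercept = 10640, slope = 57.8),
    maternal_vars = c(bw2 = 59.3, ratio = 1.17, intercept = 2771, slope = 23.0),
    genetic_corr = default_genetic_corr(),
    maternal_corr = default_maternal_corr(),
    residual_bw2 = 577.7, residual_ratio = 30.45,
    residual_bw7_classes = c(43800, 44750, 60500, 64700, 93800),
    means = c(bw2 = 248, ratio = 28.2, intercept = 2080),
    population_slope = -14.6, threshold = 29, edges = c(0, 5, 10, 15),
    mortality = 0.09, ratio_missing = 0.007, bw2_missing = 0.0016,
    n_batches = 5, n_stables = 2, n_cutters = 11,
    gender_bw2 = c(m = 8, f = -8), gender_bw7 = c(m = 60, f = -60),
    gender_ratio = c(m = 0.25, f = -0.25),
    batchstable_bw2 = centered_seq(6, n_batches * n_stables),
    batchstable_bw7 = centered_seq(40, n_batches * n_stables),
    batchstable_ratio = centered_seq(0.4, n_batches * n_stables),
    age_bw2_eff = c(`12` = -3, `13` = 3),
    age_bw7_eff = c(`45` = -15, `46` = 15),
    age_ratio_eff = c(`46` = -0.2, `47` = 0, `48` = 0.2),
    cutter_ratio = centered_seq(0.6, n_cutters),
    slope_batchstable = centered_seq(1.5, n_batches * n_stables),
    slope_cutter = centered_seq(1.0, n_cutters)) {
  traits <- c("bw2", "ratio", "intercept", "slope")
  stopifnot(all(traits %in% names(genetic_vars)),
            all(traits %in% names(maternal_vars)),
            all(genetic_vars >= 0), all(maternal_vars >= 0),
            residual_bw2 >= 0, residual_ratio >= 0,
            all(residual_bw7_classes >= 0),
            length(residual_bw7_classes) == length(edges) + 1L,
            mortality >= 0, mortality < 1, n_sires >= 1)
  cfg <- list(
    n_sires = n_sires, n_dams = n_dams, n_offspring = n_offspring,
    nested = nested, dams_per_sire = dams_per_sire,
    offspring_per_dam = offspring_per_dam,
    sires_per_dam_probs = sires_per_dam_probs,
    genetic_vars = genetic_vars[traits], maternal_vars = maternal_vars[traits],
    genetic_corr = repair_corr(genetic_corr, "genetic"),
    maternal_corr = repair_corr(maternal_corr, "maternal"),
    residual_bw2 = residual_bw2, residual_ratio = residual_ratio,
    residual_bw7_classes = residual_bw7_classes,
    means = means, population_slope = population_slope,
    threshold = threshold, edges = edges,
    mortality = mortality, ratio_missing = ratio_missing,
    bw2_missing = bw2_missing,
    n_batches = n_batches, n_stables = n_stables, n_cutters = n_cutters,
    gender_bw2 = gender_bw2, gender_bw7 = gender_bw7,
    gender_ratio = gender_ratio,
    batchstable_bw2 = batchstable_bw2, batchstable_bw7 = batchstable_bw7,
    batchstable_ratio = batchstable_ratio,
    age_bw2_eff = age_bw2_eff, age_bw7_eff = age_bw7_eff,
    age_ratio_eff = age_ratio_eff, cutter_ratio = cutter_ratio,
    slope_batchstable = slope_batchstable, slope_cutter = slope_cutter)
  class(cfg) <- "sim_config"
  cfg
}

# evenly spaced centered level effects of half-range `half`
centered_seq <- function(half, n) {
  v <- seq(-half, half, length.out = n)
  v - mean(v)
}

#' Table-derived default correlation structures
#'
#' Genetic (above-diagonal) and maternal (below-diagonal) correlations over
#' (BW2, RATIO, INTERCEPT, SLOPE) used as generator defaults.
#' @export
default_genetic_corr <- function() {
  corr4(bw2_ratio = 0.09, bw2_intercept = 0.71, bw2_slope = -0.27,
        ratio_intercept = 0.15, ratio_slope = -0.36,
        intercept_slope = -0.30)
}

#' @rdname default_genetic_corr
#' @export
default_maternal_corr <- function() {
  corr4(bw2_ratio = -0.31, bw2_intercept = 0.76, bw2_slope = -0.005,
        ratio_intercept = 0.003, ratio_slope = -0.80,
        intercept_slope = -0.26)
}

corr4 <- function(bw2_ratio, bw2_intercept, bw2_slope,
                  ratio_intercept, ratio_slope, intercept_slope) {
  traits <- c("bw2", "ratio", "intercept", "slope")
  m <- diag(4)
  dimnames(m) <- list(traits, traits)
  m["bw2", "ratio"] <- m["ratio", "bw2"] <- bw2_ratio
  m["bw2", "intercept"] <- m["intercept", "bw2"] <- bw2_intercept
  m["bw2", "slope"] <- m["slope", "bw2"] <- bw2_slope
  m["ratio", "intercept"] <- m["intercept", "ratio"] <- ratio_intercept
  m["ratio", "slope"] <- m["slope", "ratio"] <- ratio_slope
  m["intercept", "slope"] <- m["slope", "intercept"] <- intercept_slope
  m
}

# nearest-PSD repair by eigenvalue clipping, rescaled to unit diagonal
repair_corr <- function(m, label) {
  stopifnot(is.matrix(m), nrow(m) == 4, ncol(m) == 4)
  if (is.null(dimnames(m))) {
    dimnames(m) <- rep(list(c("bw2", "ratio", "intercept", "slope")), 2)
  }
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(m)
  v <- pmax(e$values, 1e-8)
  r <- e$vectors %*% diag(v) %*% t(e$vectors)
  r <- stats::cov2cor(r)
  dimnames(r) <- dimnames(m)
  warning("rounded ", label, " correlation matrix was not positive ",
          "semidefinite; projected to the nearest PSD correlation matrix ",
          "(largest adjustment ", format(max(abs(r - m)), digits = 3), ")")
  r
}

#' Reduced-scale simulation presets
#'
#' * `"paper"`: the full study design (83 sires, 788 dams, 7722 offspring,
#'   cross-classified matings).
#' * `"small"`: nested 40 sires x 8 dams x 10 offspring (3200 offspring),
#'   the reduced scale used for replicate parameter-recovery studies.
#' * `"large"`: nested 50 sires x 10 dams x 10 offspring (5000 offspring).
#'
#' @param preset preset name.
#' @param ... overrides passed on to [sim_config()].
#' @export
sim_preset <- function(preset = c("small", "paper", "large"), ...) {
  preset <- match.arg(preset)
  switch(preset,
    paper = sim_config(...),
    small = sim_config(nested = TRUE, n_sires = 40, dams_per_sire = 8,
                       offspring_per_dam = 10, ...),
    large = sim_config(nested = TRUE, n_sires = 50, dams_per_sire = 10,
                       offspring_per_dam = 10, ...))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Simulate the mating design and pedigree
#'
#' Founder sires and dams, sire x dam matings (nested or cross-classified
#' with a configurable sires-per-dam distribution), offspring assigned to
#' matings, and the structural factors (gender, batch, stable, cutter,
#' recording ages) drawn for each offspring.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical config + seed gives identical output.
#' @return list with `pedigree` (a [new_pedigree()]) and `meta` (data frame
#'   of per-offspring structural factors).
#' @export
simulate_pedigree <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    sires <- paste0("s", seq_len(config$n_sires))
    if (config$nested) {
      n_dams <- config$n_sires * config$dams_per_sire
      dams <- paste0("d", seq_len(n_dams))
      dam_sire <- rep(sires, each = config$dams_per_sire)
      off_dam <- rep(dams, each = config$offspring_per_dam)
      off_sire <- rep(dam_sire, each = config$offspring_per_dam)
    } else {
      n_dams <- config$n_dams
      dams <- paste0("d", seq_len(n_dams))
      k <- sample(seq_along(config$sires_per_dam_probs), n_dams,
                  replace = TRUE, prob = config$sires_per_dam_probs)
      pair_dam <- rep(dams, k)
      pair_sire <- unlist(lapply(k, function(m) sample(sires, m)))
      m_idx <- sample(length(pair_dam), config$n_offspring, replace = TRUE)
      off_dam <- pair_dam[m_idx]
      off_sire <- pair_sire[m_idx]
    }
    n_off <- length(off_dam)
    offspring <- paste0("o", seq_len(n_off))
    ped <- new_pedigree(
      animal = c(sires, dams, offspring),
      sire = c(rep(NA, config$n_sires + n_dams), off_sire),
      dam = c(rep(NA, config$n_sires + n_dams), off_dam))
    meta <- data.frame(
      animal = offspring, sire = off_sire, dam = off_dam,
      gender = sample(c("m", "f"), n_off, replace = TRUE),
      batch = sample(seq_len(config$n_batches), n_off, replace = TRUE),
      stable = sample(seq_len(config$n_stables), n_off, replace = TRUE),
      person = sample(seq_len(config$n_cutters), n_off, replace = TRUE),
      age_bw2 = sample(as.integer(names(config$age_bw2_eff)), n_off, replace = TRUE),
      age_bw7 = sample(as.integer(names(config$age_bw7_eff)), n_off, replace = TRUE),
      age_ratio = sample(as.integer(names(config$age_ratio_eff)), n_off, replace = TRUE),
      stringsAsFactors = FALSE)
    list(pedigree = ped, meta = meta)
  })
}

# PSD-safe multivariate normal draws (rows) via eigen square root
rmvn_psd <- function(n, sigma) {
  p <- ncol(sigma)
  if (all(sigma == 0)) return(matrix(0, n, p, dimnames = list(NULL, colnames(sigma))))
  e <- eigen(sigma, symmetric = TRUE)
  rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  z <- matrix(stats::rnorm(n * p), n, p)
  out <- z %*% rt
  colnames(out) <- colnames(sigma)
  out
}

#' Simulate correlated additive-genetic and maternal values
#'
#' Founders are drawn from the 4-variate additive distribution implied by
#' the configured variances and correlations; descendants are the parent
#' average plus a Mendelian-sampling deviation with covariance
#' `0.5 * (1 - (F_s + F_d) / 2) * Sigma`. Maternal (dam-environment)
#' 4-vectors are drawn independently per dam.
#'
#' @param ped a pedigree (or the list returned by [simulate_pedigree()]).
#' @inheritParams simulate_pedigree
#' @return list with `additive` (animals x 4 matrix), `maternal`
#'   (dams x 4 matrix), and the covariance matrices used (`sigma_g`,
#'   `sigma_m`).
#' @export
simulate_genetic_values <- function(ped, config, seed = 1) {
  if (is.list(ped) && !inherits(ped, "pedigree")) ped <- ped$pedigree
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  sds_g <- sqrt(config$genetic_vars)
  sds_m <- sqrt(config$maternal_vars)
  sigma_g <- diag(sds_g) %*% config$genetic_corr %*% diag(sds_g)
  sigma_m <- diag(sds_m) %*% config$maternal_corr %*% diag(sds_m)
  dimnames(sigma_g) <- dimnames(sigma_m) <- dimnames(config$genetic_corr)
  with_seed(seed, {
    n <- nrow(ped)
    idx <- stats::setNames(seq_len(n), ped$animal)
    si <- ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire]))
    di <- ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
    a <- matrix(0, n, 4, dimnames = list(ped$animal, colnames(sigma_g)))
    founders <- si == 0L & di == 0L
    a[founders, ] <- rmvn_psd(sum(founders), sigma_g)
    rest <- which(!founders)
    if (length(rest)) {
      # Mendelian-sampling deviations drawn jointly, scaled per animal
      ms <- rmvn_psd(length(rest), sigma_g)
      for (r in seq_along(rest)) {
        i <- rest[r]
        pa <- numeric(4)
        fbar <- 0
        np <- 0L
        if (si[i] > 0L) { pa <- pa + a[si[i], ]; fbar <- fbar + ped$f[si[i]]; np <- np + 1L }
        if (di[i] > 0L) { pa <- pa + a[di[i], ]; fbar <- fbar + ped$f[di[i]]; np <- np + 1L }
        # with one unknown parent the missing parent is an unrelated
        # non-inbred founder contributing half the additive variance
        msvar <- switch(np + 1L, 1, 0.75 - 0.25 * fbar,
                        0.5 * (1 - fbar / 2))
        a[i, ] <- pa / 2 + sqrt(msvar) * ms[r, ]
      }
    }
    dams <- unique(ped$dam[!is.na(ped$dam)])
    m <- rmvn_psd(length(dams), sigma_m)
    rownames(m) <- dams
    list(additive = a, maternal = m, sigma_g = sigma_g, sigma_m = sigma_m)
  })
}

#' Simulate phenotypes
#'
#' Builds the per-bird records: heart ratio as a single normal trait
#' (mean + fixed effects + additive + maternal + residual), the
#' plateau-coded severity, and 7-week weight as intercept plus
#' (population slope + fixed slope offsets + additive slope + maternal
#' slope) times severity with a class-specific residual; 2-week weight
#' analogously without the slope part. A configurable fraction of birds
#' loses the 7-week records (mortality).
#'
#' @param pedinfo the list returned by [simulate_pedigree()].
#' @param values the list returned by [simulate_genetic_values()].
#' @inheritParams simulate_pedigree
#' @return list with `phenotypes` (a phenotype table) and `truth`
#'   (generating parameters plus per-animal true values).
#' @export
simulate_phenotypes <- function(pedinfo, values, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  meta <- pedinfo$meta
  with_seed(seed, {
    n <- nrow(meta)
    av <- values$additive[meta$animal, , drop = FALSE]
    mv <- values$maternal[meta$dam, , drop = FALSE]
    cell <- (meta$batch - 1L) * config$n_stables + meta$stable
    fe_bw2 <- config$gender_bw2[meta$gender] +
      config$batchstable_bw2[cell] +
      config$age_bw2_eff[as.character(meta$age_bw2)]
    fe_ratio <- config$gender_ratio[meta$gender] +
      config$batchstable_ratio[cell] +
      config$age_ratio_eff[as.character(meta$age_ratio)] +
      config$cutter_ratio[meta$person]
    fe_bw7 <- config$gender_bw7[meta$gender] +
      config$batchstable_bw7[cell] +
      config$age_bw7_eff[as.character(meta$age_bw7)]
    bw2 <- config$means["bw2"] + fe_bw2 + av[, "bw2"] + mv[, "bw2"] +
      stats::rnorm(n, 0, sqrt(config$residual_bw2))
    ratio <- config$means["ratio"] + fe_ratio + av[, "ratio"] + mv[, "ratio"] +
      stats::rnorm(n, 0, sqrt(config$residual_ratio))
    t <- code_ratioplat(ratio, config$threshold)
    cls <- residual_class(t, config$edges)
    slope <- config$population_slope + config$slope_batchstable[cell] +
      config$slope_cutter[meta$person] + av[, "slope"] + mv[, "slope"]
    bw7 <- config$means["intercept"] + fe_bw7 + av[, "intercept"] +
      mv[, "intercept"] + slope * t +
      stats::rnorm(n, 0, sqrt(config$residual_bw7_classes[cls]))
    dead <- stats::runif(n) < config$mortality
    ratio_only <- stats::runif(n) < config$ratio_missing
    bw2_na <- stats::runif(n) < config$bw2_missing
    bw7[dead] <- NA
    ratio[dead | ratio_only] <- NA
    bw2[bw2_na] <- NA
    pheno <- data.frame(
      animal = meta$animal, sire = meta$sire, dam = meta$dam,
      gender = meta$gender, batch = meta$batch, stable = meta$stable,
      age_bw2 = meta$age_bw2, age_bw7 = meta$age_bw7,
      age_ratio = meta$age_ratio, person = meta$person,
      bw2 = unname(bw2), bw7 = unname(bw7), ratio = unname(ratio),
      stringsAsFactors = FALSE)
    class(pheno) <- c("phenotype_table", "data.frame")
    truth <- list(config = config, additive = values$additive,
                  maternal = values$maternal, sigma_g = values$sigma_g,
                  sigma_m = values$sigma_m,
                  true_severity = stats::setNames(unname(t), meta$animal),
                  true_class = stats::setNames(unname(cls), meta$animal))
    list(phenotypes = pheno, truth = truth)
  })
}

#' Simulate a full population
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genetic_values()] and [simulate_phenotypes()] with seeds
#' derived from `seed` (seed, seed + 1, seed + 2).
#'
#' @inheritParams simulate_pedigree
#' @return list with `pedigree`, `meta`, `phenotypes`, `truth`.
#' @export
simulate_population <- function(config = sim_preset("small"), seed = 1) {
  pedinfo <- simulate_pedigree(config, seed)
  values <- simulate_genetic_values(pedinfo$pedigree, config, seed + 1L)
  sim <- simulate_phenotypes(pedinfo, values, config, seed + 2L)
  list(pedigree = pedinfo$pedigree, meta = pedinfo$meta,
       phenotypes = sim$phenotypes, truth = sim$truth)
}
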