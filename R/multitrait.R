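# Joint (multi-response) animal models: two trait-mean responses, or one
# trait-mean response together with the 7-week-weight reaction norm. Both
# reuse the single-trait machinery by stacking records, block-diagonal
# fixed designs, random terms with one correlated effect column per
# response, and an animal-blocked residual with a cross-trait correlation.

mean_spec_for <- function(trait) {
  if (trait == "ratio") model2_spec() else model1_spec(trait)
}

#' Bivariate animal model
#'
#' Joint REML fit of two trait-mean animal models with unstructured 2x2
#' additive-genetic, dam, and residual (co)variance; the residual
#' covariance contributes only for animals with both traits observed.
#' Genetic, maternal and phenotypic correlations (the latter from summed
#' components) are derivable with [bivariate_correlations()].
#'
#' @param trait_a,trait_b two of `"bw2"`, `"bw7"`, `"ratio"`.
#' @param pheno phenotype table.
#' @param ped pedigree.
#' @param se,control passed to [reml_fit()].
#' @return a [reml_fit()] object; component names carry the trait labels.
#' @export
bivariate_fit <- function(trait_a, trait_b, pheno, ped,
                          se = c("hessian", "none"),
                          control = reml_control()) {
  se <- match.arg(se)
  stopifnot(trait_a != trait_b)
  parts <- lapply(c(trait_a, trait_b), function(tr) {
    spec <- mean_spec_for(tr)
    rows <- !is.na(pheno[[tr]])
    df <- pheno[rows, , drop = FALSE]
    fx <- fixed_design(spec, df, sev = NULL, prefix = paste0(tr, ":"))
    list(trait = tr, df = df, y = df[[tr]], X = fx$X,
         design_row = NULL)
  })
  design <- joint_design(parts, ped,
                         design_cols = function(part, slot, nslot) {
                           d <- matrix(0, nrow(part$df), nslot)
                           d[, slot] <- 1
                           colnames(d) <- vapply(parts, `[[`, character(1), "trait")
                           d
                         },
                         var_class = function(part, slot) rep(slot, nrow(part$df)),
                         var_labels = c(trait_a, trait_b))
  reml_fit(design, se = se, control = control)
}

#' Joint fit of a trait with the reaction-norm tolerance model
#'
#' Extends the tolerance analysis with a second trait (2-week weight or
#' heart ratio): the animal (pedigree) and dam (independent) terms carry an
#' unstructured 3x3 block over (trait additive effect, reaction-norm
#' intercept, reaction-norm slope), the 7-week-weight part keeps its fixed
#' slope terms and five-class residual, and a single residual correlation
#' links the two traits' records of the same animal across classes.
#'
#' @param trait `"bw2"` or `"ratio"`.
#' @inheritParams bivariate_fit
#' @param threshold,edges plateau coding of the severity covariate.
#' @return a [reml_fit()] object.
#' @export
extended_fit <- function(trait = c("bw2", "ratio"), pheno, ped,
                         se = c("hessian", "none"),
                         control = reml_control(),
                         threshold = 29, edges = c(0, 5, 10, 15)) {
  trait <- match.arg(trait)
  se <- match.arg(se)
  spec_a <- mean_spec_for(trait)
  rows_a <- !is.na(pheno[[trait]])
  df_a <- pheno[rows_a, , drop = FALSE]
  fx_a <- fixed_design(spec_a, df_a, sev = NULL, prefix = paste0(trait, ":"))

  spec_b <- model3_spec(threshold = threshold, edges = edges)
  rows_b <- !is.na(pheno$bw7) & !is.na(pheno$ratio)
  df_b <- pheno[rows_b, , drop = FALSE]
  sev_b <- code_ratioplat(df_b$ratio, threshold)
  cls_b <- residual_class(sev_b, edges)
  fx_b <- fixed_design(spec_b, df_b, sev = sev_b, prefix = "bw7:")

  cls_present <- sort(unique(cls_b))
  parts <- list(
    list(trait = trait, df = df_a, y = df_a[[trait]], X = fx_a$X, sev = NULL,
         cls = rep(1L, nrow(df_a))),
    list(trait = "bw7", df = df_b, y = df_b$bw7, X = fx_b$X, sev = sev_b,
         cls = 1L + match(cls_b, cls_present)))
  design <- joint_design(parts, ped,
    design_cols = function(part, slot, nslot) {
      d <- matrix(0, nrow(part$df), 3)
      colnames(d) <- c(trait, "intercept", "slope")
      if (slot == 1L) d[, 1] <- 1 else { d[, 2] <- 1; d[, 3] <- part$sev }
      d
    },
    var_class = function(part, slot) part$cls,
    var_labels = c(trait, paste0("class", cls_present)))
  reml_fit(design, se = se, control = control)
}

# stack parts into one mm_design with animal-blocked residual
joint_design <- function(parts, ped, design_cols, var_class, var_labels) {
  nslot <- length(parts)
  y <- unlist(lapply(parts, `[[`, "y"), use.names = FALSE)
  X <- do.call(Matrix::bdiag, lapply(parts, `[[`, "X"))
  colnames(X) <- unlist(lapply(parts, function(p) colnames(p$X)))
  n <- length(y)
  animal_ids <- unlist(lapply(parts, function(p) p$df$animal), use.names = FALSE)
  dam_ids <- unlist(lapply(parts, function(p) p$df$dam), use.names = FALSE)
  dmat <- do.call(rbind, lapply(seq_along(parts), function(i) {
    design_cols(parts[[i]], i, nslot)
  }))
  terms <- list(
    build_term("animal", "ped", animal_ids, dmat, ped),
    build_term("dam", "iid", dam_ids, dmat, ped))
  names(terms) <- c("animal", "dam")
  vc <- unlist(lapply(seq_along(parts), function(i) var_class(parts[[i]], i)),
               use.names = FALSE)
  slot <- rep(seq_along(parts), vapply(parts, function(p) nrow(p$df), numeric(1)))
  resid <- list(type = "cross", var_class = as.integer(vc),
                var_labels = var_labels,
                block_id = match(animal_ids, unique(animal_ids)),
                slot = as.integer(slot), pairs = list(c(1L, 2L)))
  structure(list(y = y, X = methods::as(X, "CsparseMatrix"),
                 avg_deriv = NULL, n = n, terms = terms, resid = resid,
                 spec = NULL, row_animal = animal_ids),
            class = "mm_design")
}

#' Correlations implied by a bivariate fit
#'
#' Genetic, maternal (dam) and phenotypic correlations from the components
#' of a [bivariate_fit()], with delta-method standard errors. The
#' phenotypic correlation is computed from the summed (co)variance
#' components, matching the animal-model framing.
#'
#' @param fit a [bivariate_fit()] result.
#' @return data frame with rows genetic/maternal/phenotypic.
#' @export
bivariate_correlations <- function(fit) {
  nms <- names(fit$components)
  traits <- sub("^animal\\.var_", "", grep("^animal\\.var_", nms, value = TRUE))
  stopifnot(length(traits) == 2L)
  a <- traits[1]; b <- traits[2]
  cov_nm <- grep("^animal\\.cov_", nms, value = TRUE)
  dcov_nm <- grep("^dam\\.cov_", nms, value = TRUE)
  f_g <- function(ph) ph[[cov_nm]] / sqrt(ph[[paste0("animal.var_", a)]] *
                                          ph[[paste0("animal.var_", b)]])
  f_m <- function(ph) ph[[dcov_nm]] / sqrt(ph[[paste0("dam.var_", a)]] *
                                           ph[[paste0("dam.var_", b)]])
  f_p <- function(ph) {
    va <- ph[[paste0("animal.var_", a)]] + ph[[paste0("dam.var_", a)]] +
      ph[[paste0("residual.", a)]]
    vb <- ph[[paste0("animal.var_", b)]] + ph[[paste0("dam.var_", b)]] +
      ph[[paste0("residual.", b)]]
    cab <- ph[[cov_nm]] + ph[[dcov_nm]] +
      ph[["residual.rho1"]] * sqrt(ph[[paste0("residual.", a)]] *
                                   ph[[paste0("residual.", b)]])
    cab / sqrt(va * vb)
  }
  rows <- lapply(list(genetic = f_g, maternal = f_m, phenotypic = f_p),
                 function(f) delta_se(fit, f))
  data.frame(correlation = names(rows),
             estimate = vapply(rows, `[[`, numeric(1), "value"),
             se = vapply(rows, `[[`, numeric(1), "se"),
             row.names = NULL)
}
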