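#' Trait-mean animal model for body weights
#'
#' Fixed gender, batch-by-stable interaction and recording age; a random
#' pedigree-additive animal effect and an independent (no pedigree) random
#' dam effect; homogeneous residual.
#'
#' @param trait `"bw2"` or `"bw7"`.
#' @return a [model_spec()].
#' @export
model1_spec <- function(trait = c("bw2", "bw7")) {
  trait <- match.arg(trait)
  model_spec(response = trait,
             fixed_terms = c("gender", "batch_stable", "age"),
             random = list(
               list(name = "animal", id = "animal", structure = "ped",
                    design = "intercept"),
               list(name = "dam", id = "dam", structure = "iid",
                    design = "intercept")),
             residual = "homogeneous")
}

#' Trait-mean animal model for heart ratio
#'
#' As [model1_spec()] with the additional fixed effect of the heart cutter.
#'
#' @return a [model_spec()].
#' @export
model2_spec <- function() {
  model_spec(response = "ratio",
             fixed_terms = c("gender", "batch_stable", "age", "person"),
             random = list(
               list(name = "animal", id = "animal", structure = "ped",
                    design = "intercept"),
               list(name = "dam", id = "dam", structure = "iid",
                    design = "intercept")),
             residual = "homogeneous")
}

#' Random-regression tolerance model
#'
#' 7-week body weight regressed on plateau-coded heart-ratio severity:
#' correlated random intercept and slope at the animal level (with
#' pedigree) and at the dam level (independent), fixed gender,
#' batch-by-stable, age and cutter effects, a fixed population slope with
#' batch-by-stable and cutter slope interactions, and one residual variance
#' per severity class.
#'
#' @param include_bw2_covariate include 2-week weight as a fixed covariate,
#'   accounting for a possible dependence of ascites on initial growth.
#' @param threshold plateau threshold in percent.
#' @param edges residual-class edges.
#' @param linear fit the linear (non-plateau) severity covariate instead;
#'   used for model comparison.
#' @return a [model_spec()].
#' @export
model3_spec <- function(include_bw2_covariate = FALSE, threshold = 29,
                        edges = c(0, 5, 10, 15), linear = FALSE) {
  fixed <- c("gender", "batch_stable", "age", "person", "slope_terms")
  if (include_bw2_covariate) fixed <- c(fixed, "bw2_covariate")
  model_spec(response = "bw7", fixed_terms = fixed,
             random = list(
               list(name = "animal", id = "animal", structure = "ped",
                    design = "reaction_norm"),
               list(name = "dam", id = "dam", structure = "iid",
                    design = "reaction_norm")),
             residual = "severity_classes",
             threshold = threshold, edges = edges, linear = linear)
}

#' Intercept-slope covariance block of a tolerance fit
#'
#' Extracts the 2x2 (co)variance block of a random reaction-norm term from
#' a fitted tolerance model as a [gencov2()].
#'
#' @param fit a [reml_fit()] of [model3_spec()].
#' @param term `"animal"` (genetic) or `"dam"` (maternal).
#' @export
gencov2_from_fit <- function(fit, term = c("animal", "dam")) {
  term <- match.arg(term)
  ph <- fit$components
  gencov2(var_intercept = ph[[paste0(term, ".var_intercept")]],
          var_slope = ph[[paste0(term, ".var_slope")]],
          cov_intercept_slope = ph[[paste0(term, ".cov_intercept_slope")]])
}

#' Residual variances per severity class from a tolerance fit
#'
#' @param fit a [reml_fit()] of [model3_spec()].
#' @return numeric vector of class residual variances in class order.
#' @export
residual_classes_from_fit <- function(fit) {
  sel <- grepl("^residual\\.class", names(fit$components))
  unname(fit$components[sel])
}

#' Run the full analysis sequence
#'
#' Reproduces the study's output surface on one data set: trait-mean fits
#' for BW2, BW7 and RATIO, the random-regression tolerance model with and
#' without the BW2 covariate, covariance-function trajectories, EBV
#' distribution summaries, and a component significance table. Stages that
#' fail to converge are recorded and dependent stages skipped with a note.
#'
#' @param pheno phenotype table.
#' @param ped pedigree.
#' @param config list of options: `se` (`"hessian"`/`"none"`),
#'   `threshold`, `edges`, `grid`, `with_covariate` (also fit the
#'   BW2-covariate tolerance model), `control`.
#' @return list of class `analysis_bundle` with elements `mean_fits`,
#'   `tolerance`, `tolerance_bw2cov`, `trajectories`, `ebv`,
#'   `significance`, `notes`.
#' @export
run_full_analysis <- function(pheno, ped, config = list()) {
  if (nrow(pheno) == 0L) stop("empty phenotype table")
  se <- config$se %||% "hessian"
  threshold <- config$threshold %||% 29
  edges <- config$edges %||% c(0, 5, 10, 15)
  grid <- config$grid %||% seq(0, 20, by = 0.5)
  control <- config$control %||% reml_control()
  with_cov <- config$with_covariate %||% TRUE
  notes <- character(0)

  mean_fits <- list()
  for (tr in c("bw2", "bw7", "ratio")) {
    spec <- if (tr == "ratio") model2_spec() else model1_spec(tr)
    mean_fits[[tr]] <- tryCatch(
      reml_fit(spec, pheno, ped, se = se, control = control),
      error = function(e) {
        notes <<- c(notes, paste0("mean model for ", tr, " failed: ",
                                  conditionMessage(e)))
        NULL
      })
  }

  tol <- tryCatch(
    reml_fit(model3_spec(threshold = threshold, edges = edges), pheno, ped,
             se = se, control = control),
    error = function(e) {
      notes <<- c(notes, paste0("tolerance model failed: ",
                                conditionMessage(e)))
      NULL
    })
  tol_cov <- if (with_cov) tryCatch(
    reml_fit(model3_spec(include_bw2_covariate = TRUE,
                         threshold = threshold, edges = edges),
             pheno, ped, se = se, control = control),
    error = function(e) {
      notes <<- c(notes, paste0("tolerance model with BW2 covariate failed: ",
                                conditionMessage(e)))
      NULL
    }) else NULL

  traj <- NULL
  ebv <- NULL
  if (!is.null(tol) && tol$converged) {
    cls_all <- residual_class(code_ratioplat(pheno$ratio[!is.na(pheno$ratio)],
                                             threshold), edges)
    bw7obs <- pheno$bw7[!is.na(pheno$ratio)]
    class_means <- vapply(seq_len(length(edges) + 1L), function(cc) {
      mean(bw7obs[cls_all == cc], na.rm = TRUE)
    }, numeric(1))
    v_e <- residual_classes_from_fit(tol)
    if (length(v_e) == length(edges) + 1L) {
      traj <- trajectory_ratios(gencov2_from_fit(tol, "animal"),
                                gencov2_from_fit(tol, "dam"),
                                v_e, grid = grid, threshold = threshold,
                                edges = edges, class_means = class_means)
    } else {
      notes <- c(notes, "trajectories skipped: empty severity classes")
    }
    ebv <- list(
      offspring = ebv_summary(tol, ped, "offspring", "animal", "slope"),
      sires = ebv_summary(tol, ped, "sires", "animal", "slope"),
      dams = ebv_summary(tol, ped, "dams", "dam", "slope"))
  } else if (!is.null(tol)) {
    notes <- c(notes, "trajectories and EBV summaries skipped: tolerance model did not converge")
  }

  sig <- significance_table(c(mean_fits, list(tolerance = tol)))
  structure(list(mean_fits = mean_fits, tolerance = tol,
                 tolerance_bw2cov = tol_cov, trajectories = traj,
                 ebv = ebv, significance = sig, notes = notes),
            class = "analysis_bundle")
}

significance_table <- function(fits) {
  rows <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    if (is.null(fit)) next
    for (cn in names(fit$components)) {
      if (grepl("\\.cov_|rho", cn)) next
      est <- fit$components[[cn]]
      sev <- fit$se[[cn]]
      call <- if (is.na(sev)) NA else
        variance_significant(est, sev)$significant
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, component = cn, estimate = est, se = sev,
        significant = call)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
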