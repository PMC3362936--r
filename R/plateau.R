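#' Plateau-linear coding of the disease-severity covariate
#'
#' Heart ratio (right-ventricle weight as a percentage of total heart
#' weight) is an indicator of ascites. Body weight is expected to respond
#' to heart ratio only above a disease threshold, so the severity covariate
#' is coded plateau-linear: values at or below the threshold map to zero,
#' values above it to their excess over the threshold.
#'
#' @param ratio heart ratio in percent, in (0, 100).
#' @param threshold plateau threshold in percent (default 29).
#' @return `pmax(0, ratio - threshold)`, the severity covariate.
#' @examples
#' code_ratioplat(c(28, 29, 35))  # 0, 0, 6
#' @export
code_ratioplat <- function(ratio, threshold = 29) {
  stopifnot(is.numeric(ratio), is.numeric(threshold), length(threshold) == 1L)
  pmax(0, ratio - threshold)
}

#' Back-transform a severity value to the heart-ratio scale
#'
#' Inverse of [code_ratioplat()] on the affected branch: adds the threshold
#' back, so trajectory grids can be reported in original heart-ratio percent.
#'
#' @param ratioplat non-negative severity values.
#' @inheritParams code_ratioplat
#' @export
back_transform <- function(ratioplat, threshold = 29) {
  stopifnot(all(ratioplat >= 0))
  ratioplat + threshold
}

#' Residual-variance class of a severity value
#'
#' The random-regression model estimates a separate residual variance in
#' five severity classes so that residual heterogeneity does not inflate the
#' genetic slope variance. Class 1 is reserved for the exactly-healthy point
#' (severity 0); the remaining classes are left-open/right-closed intervals
#' on the default edges 0-5, 5-10, 10-15 and > 15.
#'
#' @param ratioplat non-negative severity values.
#' @param edges strictly increasing interval edges; `edges[1]` must be 0.
#' @return integer class index in `1:(length(edges) + 1)`.
#' @examples
#' residual_class(c(0, 3, 17.5))  # 1, 2, 5
#' @export
residual_class <- function(ratioplat, edges = c(0, 5, 10, 15)) {
  if (any(ratioplat < 0)) stop("severity values must be non-negative")
  stopifnot(edges[1] == 0, !is.unsorted(edges, strictly = TRUE))
  cls <- findInterval(ratioplat, edges, left.open = TRUE) + 1L
  cls[ratioplat == 0] <- 1L
  cls
}

#' Plateau configuration
#'
#' Bundles the plateau threshold, the candidate thresholds scanned by
#' information criteria, and the residual-class edges.
#'
#' @param threshold selected threshold in percent.
#' @param candidate_range thresholds scanned by [threshold_scan()].
#' @param residual_class_edges edges passed to [residual_class()].
#' @export
plateau_config <- function(threshold = 29, candidate_range = c(27, 28, 29, 30),
                           residual_class_edges = c(0, 5, 10, 15)) {
  stopifnot(threshold %in% candidate_range,
            all(diff(residual_class_edges) > 0),
            residual_class_edges[1] == 0)
  structure(list(threshold = threshold, candidate_range = candidate_range,
                 residual_class_edges = residual_class_edges),
            class = "plateau_config")
}

#' Information-criterion scan over plateau thresholds
#'
#' Fits the random-regression tolerance model at each candidate threshold
#' and returns AIC/BIC per candidate together with the AIC-minimizing
#' threshold. Candidates whose fit fails or does not converge are flagged
#' and excluded from the argmin. Successive fits are warm-started from the
#' previous candidate's estimates.
#'
#' @param pheno a phenotype table (see [read_phenotypes()]).
#' @param ped a pedigree object.
#' @param candidates numeric vector of thresholds in percent.
#' @param include_bw2_covariate logical; include 2-week weight as a fixed
#'   covariate in the tolerance model.
#' @param control a [reml_control()] list.
#' @return a list with `table` (data frame: threshold, logL, aic, bic,
#'   converged) and `selected` (the AIC-minimizing converged threshold).
#' @export
threshold_scan <- function(pheno, ped, candidates = c(27, 28, 29, 30),
                           include_bw2_covariate = FALSE,
                           control = reml_control()) {
  stopifnot(length(candidates) >= 1L)
  rows <- vector("list", length(candidates))
  start <- NULL
  for (ci in seq_along(candidates)) {
    th <- candidates[ci]
    fit <- tryCatch({
      spec <- model3_spec(include_bw2_covariate = include_bw2_covariate,
                          threshold = th)
      reml_fit(spec, pheno, ped, start = start, se = "none", control = control)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[ci]] <- data.frame(threshold = th, logL = NA_real_,
                               aic = NA_real_, bic = NA_real_,
                               converged = FALSE)
    } else {
      start <- fit$theta
      rows[[ci]] <- data.frame(threshold = th, logL = fit$logL,
                               aic = fit$aic, bic = fit$bic,
                               converged = fit$converged)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- tab$converged & is.finite(tab$aic)
  selected <- if (any(ok)) tab$threshold[ok][which.min(tab$aic[ok])] else NA_real_
  list(table = tab, selected = selected)
}

#' Compare the plateau-linear and linear tolerance models
#'
#' Fits the tolerance model twice: once with the plateau-coded severity
#' covariate and once with a linear covariate (heart ratio shifted to start
#' at its observed minimum, i.e. the threshold placed below all data so the
#' plateau branch is empty). Residual classes are assigned from the plateau
#' coding in both fits so the class structure is identical and the
#' information criteria comparable.
#'
#' @inheritParams threshold_scan
#' @param threshold plateau threshold for the plateau fit.
#' @return data frame with one row per model (plateau, linear) carrying
#'   logL, AIC, BIC and convergence flags.
#' @export
compare_plateau_linear <- function(pheno, ped, threshold = 29,
                                   control = reml_control()) {
  fit_p <- reml_fit(model3_spec(threshold = threshold), pheno, ped,
                    se = "none", control = control)
  fit_l <- reml_fit(model3_spec(threshold = threshold, linear = TRUE),
                    pheno, ped, se = "none", control = control)
  data.frame(model = c("plateau", "linear"),
             logL = c(fit_p$logL, fit_l$logL),
             aic = c(fit_p$aic, fit_l$aic),
             bic = c(fit_p$bic, fit_l$bic),
             converged = c(fit_p$converged, fit_l$converged))
}
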