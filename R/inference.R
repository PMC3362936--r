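#' Significance call for a variance component
#'
#' One-tailed convention for variances and variance ratios: the estimate is
#' called significant when it exceeds 0.98 times its standard error (i.e.
#' the interval estimate minus 0.98 SE stays above zero). Negative variance
#' estimates are flagged not significant with a warning.
#'
#' @param estimate,se numeric scalars; `se >= 0`.
#' @return list of class `significance_call` with fields `estimate`, `se`,
#'   `rule` and `significant`.
#' @export
variance_significant <- function(estimate, se) {
  stopifnot(se >= 0)
  if (is.na(estimate) || estimate < 0) {
    if (!is.na(estimate)) warning("negative variance estimate; flagged not significant")
    sig <- FALSE
  } else {
    sig <- (estimate - 0.98 * se) > 0
  }
  structure(list(estimate = estimate, se = se,
                 rule = "variance-one-tailed", significant = sig),
            class = "significance_call")
}

#' Significance call for a correlation
#'
#' Two-tailed convention: significant when `|estimate|` exceeds 1.96 times
#' its standard error.
#'
#' @param estimate correlation in `[-1, 1]`.
#' @param se non-negative standard error.
#' @return list of class `significance_call`.
#' @export
correlation_significant <- function(estimate, se) {
  stopifnot(se >= 0, is.na(estimate) || abs(estimate) <= 1 + 1e-8)
  sig <- !is.na(estimate) && (abs(estimate) - 1.96 * se) > 0
  structure(list(estimate = estimate, se = se,
                 rule = "correlation-two-tailed", significant = sig),
            class = "significance_call")
}

#' @export
print.significance_call <- function(x, ...) {
  cat(format(x$estimate, digits = 4), "+/-", format(x$se, digits = 4),
      paste0("(", x$rule, "):"),
      if (x$significant) "significant" else "not significant", "\n")
  invisible(x)
}

#' Summaries of estimated breeding values by pedigree role
#'
#' Ranges and histogram bins of BLUP solutions for a chosen random term and
#' component, restricted to a pedigree role: phenotyped offspring (animals
#' with both parents in the pedigree), sires (animals appearing as a sire),
#' or dams (animals appearing as a dam).
#'
#' @param fit a converged [reml_fit()] result with solutions.
#' @param ped the pedigree used in the fit.
#' @param group one of `"offspring"`, `"sires"`, `"dams"`.
#' @param term name of the random term (e.g. `"animal"` or `"dam"`).
#' @param component column of the term's solution matrix (e.g. `"slope"`);
#'   defaults to the first column.
#' @param bins number of histogram bins.
#' @return list with `group`, `n`, `min`, `max`, `breaks`, `counts`,
#'   and the solution vector `ebv` (named by animal id).
#' @export
ebv_summary <- function(fit, ped, group = c("offspring", "sires", "dams"),
                        term = "animal", component = NULL, bins = 20) {
  group <- match.arg(group)
  stopifnot(inherits(ped, "pedigree"))
  sol <- fit$ranef[[term]]
  if (is.null(sol)) stop("no solutions for random term '", term, "'")
  if (is.null(component)) component <- colnames(sol)[1]
  ids <- switch(group,
    offspring = ped$animal[!is.na(ped$sire) & !is.na(ped$dam)],
    sires = unique(ped$sire[!is.na(ped$sire)]),
    dams = unique(ped$dam[!is.na(ped$dam)]))
  ids <- intersect(ids, rownames(sol))
  if (!length(ids)) stop("no animals with solutions in group '", group, "'")
  ebv <- stats::setNames(sol[ids, component], ids)
  rng <- range(ebv)
  breaks <- if (diff(rng) == 0) c(rng[1] - 0.5, rng[1] + 0.5) else
    seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- as.integer(table(cut(ebv, breaks, include.lowest = TRUE)))
  list(group = group, term = term, component = component,
       n = length(ebv), min = rng[1], max = rng[2],
       breaks = breaks, counts = counts, ebv = ebv)
}
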