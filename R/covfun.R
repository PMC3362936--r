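#' Intercept-slope genetic covariance block
#'
#' The 2x2 (co)variance matrix of the random reaction-norm coefficients
#' (intercept = performance of a healthy animal, slope = tolerance). The
#' covariance function evaluates `x' G x` with `x = (1, t)'` at severity
#' `t`, yielding the genetic (or maternal) variance of performance at any
#' point along the severity trajectory.
#'
#' @param var_intercept variance of the intercept (trait units squared).
#' @param var_slope variance of the slope ((trait units per percent)^2).
#' @param cov_intercept_slope covariance between intercept and slope.
#' @return an object of class `gencov2`.
#' @examples
#' g <- gencov2(10640, 57.8, -0.30 * sqrt(10640 * 57.8))
#' trajectory_variance(g, 0)     # the intercept variance
#' correlation_with_healthy(g, 17.5)
#' @export
gencov2 <- function(var_intercept, var_slope, cov_intercept_slope = 0) {
  stopifnot(var_intercept >= 0, var_slope >= 0)
  if (var_intercept > 0 && var_slope > 0 &&
      abs(cov_intercept_slope) > sqrt(var_intercept * var_slope) + 1e-8) {
    warning("intercept-slope covariance implies |correlation| > 1; ",
            "the block is not positive semidefinite")
  }
  structure(list(var_intercept = var_intercept, var_slope = var_slope,
                 cov_intercept_slope = cov_intercept_slope),
            class = "gencov2")
}

#' @export
print.gencov2 <- function(x, ...) {
  m <- matrix(c(x$var_intercept, x$cov_intercept_slope,
                x$cov_intercept_slope, x$var_slope), 2, 2,
              dimnames = list(c("intercept", "slope"), c("intercept", "slope")))
  print(m)
  invisible(x)
}

as_matrix_gencov2 <- function(g) {
  matrix(c(g$var_intercept, g$cov_intercept_slope,
           g$cov_intercept_slope, g$var_slope), 2, 2)
}

#' Variance along the severity trajectory
#'
#' Evaluates the covariance function `x' G x = v0 + 2 t c + t^2 v1` at
#' severity `t`, where `v0`, `v1` and `c` are the intercept variance, slope
#' variance and their covariance.
#'
#' @param g a [gencov2()] block.
#' @param t non-negative severity value(s) on the plateau-coded scale.
#' @export
trajectory_variance <- function(g, t) {
  stopifnot(inherits(g, "gencov2"))
  if (any(t < 0)) stop("severity values must be non-negative")
  g$var_intercept + 2 * t * g$cov_intercept_slope + t^2 * g$var_slope
}

#' Genetic correlation between healthy and affected animals
#'
#' Correlation implied by the covariance function between the healthy point
#' (severity 0) and severity `t`:
#' `(v0 + t c) / (sqrt(v0) * sqrt(v0 + 2 t c + t^2 v1))`.
#' Equals 1 at `t = 0`; values below 1 measure genotype re-ranking between
#' healthy and affected animals.
#'
#' @inheritParams trajectory_variance
#' @export
correlation_with_healthy <- function(g, t) {
  stopifnot(inherits(g, "gencov2"))
  if (g$var_intercept <= 0) stop("intercept variance must be positive")
  if (any(t < 0)) stop("severity values must be non-negative")
  num <- g$var_intercept + t * g$cov_intercept_slope
  num / (sqrt(g$var_intercept) * sqrt(trajectory_variance(g, t)))
}

#' Variance ratios from components
#'
#' Heritability and maternal-effect ratio from genetic, maternal and
#' environmental variance components: `V_P = V_G + V_M + V_E`,
#' `h2 = V_G / V_P`, `m2 = V_M / V_P`.
#'
#' @param v_g,v_m,v_e non-negative variance components.
#' @return list with `v_p`, `h2`, `m2`.
#' @examples
#' variance_ratios(309, 59.3, 577.7)  # h2 = 0.33, m2 = 0.06
#' @export
variance_ratios <- function(v_g, v_m, v_e) {
  v_p <- v_g + v_m + v_e
  if (any(v_p <= 0)) stop("phenotypic variance must be positive")
  list(v_p = v_p, h2 = v_g / v_p, m2 = v_m / v_p)
}

#' Trajectories of variance, heritability and re-ranking along severity
#'
#' Combines the genetic and maternal intercept-slope blocks with the
#' class-specific residual variances into pointwise trajectories of
#' variance components, heritability, maternal-effect ratio, and the
#' genetic correlation with the healthy point. The residual variance at a
#' grid point is the one of the severity class containing that point, so
#' the identity `V_P = V_G + V_M + V_E` holds exactly by construction.
#'
#' @param g_gen,g_mat genetic and maternal [gencov2()] blocks.
#' @param v_e_by_class residual variances, one per severity class.
#' @param grid severity grid (plateau-coded scale); default 0 to 20 by 0.5,
#'   spanning heart ratios 29-49 percent after back-transformation.
#' @param threshold plateau threshold used for back-transformation.
#' @param edges residual-class edges (see [residual_class()]).
#' @param class_means optional mean performance per severity class; when
#'   supplied, the per-class coefficient of phenotypic variation
#'   `100 * sqrt(V_P) / mean` is computed at class-representative severities
#'   (0 and interval midpoints, with the open top class represented by its
#'   lower edge plus half the last interval width).
#' @return object of class `trajectory_summary`: list with `trajectory`
#'   (data frame over the grid) and `cv` (data frame per class, `NA` CV
#'   when `class_means` is missing).
#' @export
trajectory_ratios <- function(g_gen, g_mat, v_e_by_class,
                              grid = seq(0, 20, by = 0.5), threshold = 29,
                              edges = c(0, 5, 10, 15), class_means = NULL) {
  stopifnot(inherits(g_gen, "gencov2"), inherits(g_mat, "gencov2"))
  n_class <- length(edges) + 1L
  if (length(v_e_by_class) != n_class) {
    stop("need one residual variance per severity class (", n_class, ")")
  }
  cls <- residual_class(grid, edges)
  v_g <- trajectory_variance(g_gen, grid)
  v_m <- trajectory_variance(g_mat, grid)
  v_e <- v_e_by_class[cls]
  v_p <- v_g + v_m + v_e
  if (any(v_p <= 0)) stop("zero phenotypic variance on the trajectory grid")
  traj <- data.frame(
    ratioplat = grid,
    heart_ratio = back_transform(grid, threshold),
    v_g = v_g, v_m = v_m, v_e = v_e, v_p = v_p,
    h2 = v_g / v_p, m2 = v_m / v_p,
    r_with_healthy = correlation_with_healthy(g_gen, grid)
  )
  # class-representative severities: 0, interval midpoints, open-ended top
  width <- diff(edges)
  rep_t <- c(0, edges[-length(edges)] + width / 2,
             edges[length(edges)] + width[length(width)] / 2)
  v_p_cls <- trajectory_variance(g_gen, rep_t) +
    trajectory_variance(g_mat, rep_t) + v_e_by_class
  cv <- if (is.null(class_means)) rep(NA_real_, n_class) else {
    stopifnot(length(class_means) == n_class)
    100 * sqrt(v_p_cls) / class_means
  }
  cvtab <- data.frame(class = seq_len(n_class), rep_severity = rep_t,
                      v_p = v_p_cls, cv = cv)
  structure(list(trajectory = traj, cv = cvtab), class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("severity trajectory over", nrow(x$trajectory), "grid points;",
      "r with healthy at far end:",
      format(x$trajectory$r_with_healthy[nrow(x$trajectory)], digits = 3), "\n")
  invisible(x)
}
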