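#' Model specification for the animal-model REML engine
#'
#' Declarative description of one mixed model: the response trait, the
#' fixed-effect terms, the random terms with their covariance structure,
#' and the residual structure. Used by [build_design()] / [reml_fit()];
#' the pre-canned study models are produced by [model1_spec()],
#' [model2_spec()] and [model3_spec()].
#'
#' @param response one of `"bw2"`, `"bw7"`, `"ratio"`.
#' @param fixed_terms character subset of `"gender"`, `"batch_stable"`,
#'   `"age"`, `"person"`, `"slope_terms"` (population slope plus its
#'   batch-x-stable and cutter interactions), `"bw2_covariate"`.
#' @param random list of random terms; each a list with `name`, `id`
#'   (grouping column: `"animal"` or `"dam"`), `structure` (`"ped"` for
#'   pedigree-additive, `"iid"`), and `design` (`"intercept"` or
#'   `"reaction_norm"` for correlated intercept + severity slope).
#' @param residual `"homogeneous"` or `"severity_classes"` (one residual
#'   variance per plateau-severity class).
#' @param threshold plateau threshold for the severity covariate.
#' @param edges residual-class edges.
#' @param linear if `TRUE` the severity covariate is linear in heart ratio
#'   (shifted to start at the observed minimum) instead of plateau-coded;
#'   residual classes are still assigned from the plateau coding so model
#'   comparisons share a class structure.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response,
                       fixed_terms = c("gender", "batch_stable", "age"),
                       random = list(
                         list(name = "animal", id = "animal",
                              structure = "ped", design = "intercept"),
                         list(name = "dam", id = "dam",
                              structure = "iid", design = "intercept")),
                       residual = "homogeneous",
                       threshold = 29, edges = c(0, 5, 10, 15),
                       linear = FALSE) {
  response <- match.arg(response, c("bw2", "bw7", "ratio"))
  known <- c("gender", "batch_stable", "age", "person", "slope_terms",
             "bw2_covariate")
  if (!all(fixed_terms %in% known)) {
    stop("unknown fixed terms: ",
         paste(setdiff(fixed_terms, known), collapse = ", "))
  }
  residual <- match.arg(residual, c("homogeneous", "severity_classes"))
  n_ped <- sum(vapply(random, function(r) r$structure == "ped", logical(1)))
  if (n_ped > 1L) stop("at most one pedigree-structured term per response")
  structure(list(response = response, fixed_terms = fixed_terms,
                 random = random, residual = residual,
                 threshold = threshold, edges = edges, linear = linear),
            class = "model_spec")
}

needs_severity <- function(spec) {
  spec$residual == "severity_classes" ||
    "slope_terms" %in% spec$fixed_terms ||
    any(vapply(spec$random, function(r) r$design == "reaction_norm", logical(1)))
}

#' Assemble the mixed-model design
#'
#' Builds the response vector, the full-rank fixed design (reference-level
#' coding), the random-effect incidence matrices with their covariance
#' structure, and the residual-class assignment from a [model_spec()], a
#' phenotype table and a pedigree. Rows with a missing response or missing
#' severity/covariate information are excluded; pedigree animals without
#' records keep random-effect levels, so their breeding values are still
#' predicted.
#'
#' @param spec a [model_spec()].
#' @param pheno a phenotype table.
#' @param ped a pedigree object.
#' @return an internal design object (class `mm_design`) consumed by
#'   [reml_fit()].
#' @export
build_design <- function(spec, pheno, ped) {
  stopifnot(inherits(spec, "model_spec"), inherits(ped, "pedigree"))
  rows <- !is.na(pheno[[spec$response]])
  if (needs_severity(spec)) rows <- rows & !is.na(pheno$ratio)
  if ("bw2_covariate" %in% spec$fixed_terms) rows <- rows & !is.na(pheno$bw2)
  if (!any(rows)) stop("no usable records for response ", spec$response)
  df <- pheno[rows, , drop = FALSE]
  y <- df[[spec$response]]
  n <- length(y)

  sev <- NULL
  cls <- NULL
  if (needs_severity(spec)) {
    plat <- code_ratioplat(df$ratio, spec$threshold)
    sev <- if (spec$linear) df$ratio - min(df$ratio) else plat
    cls <- residual_class(plat, spec$edges)
  }
  fx <- fixed_design(spec, df, sev)
  resid <- if (spec$residual == "severity_classes") {
    labels <- paste0("class", sort(unique(cls)))
    list(type = "classes", var_class = match(cls, sort(unique(cls))),
         var_labels = labels, block_id = seq_len(n),
         slot = rep(1L, n), pairs = list())
  } else {
    list(type = "classes", var_class = rep(1L, n), var_labels = "var",
         block_id = seq_len(n), slot = rep(1L, n), pairs = list())
  }

  terms <- lapply(spec$random, function(r) {
    make_random_term(r, df, ped, sev, n)
  })
  names(terms) <- vapply(terms, `[[`, character(1), "name")

  structure(list(y = y, X = fx$X, avg_deriv = fx$avg_deriv, n = n,
                 terms = terms, resid = resid, spec = spec,
                 row_animal = df$animal),
            class = "mm_design")
}

# fixed design with reference-level coding, rank check, and the average
# derivative of the fixed part with respect to severity (population slope)
fixed_design <- function(spec, df, sev, prefix = "") {
  dat <- data.frame(row.names = seq_len(nrow(df)))
  parts <- character(0)
  add_factor <- function(dat, col, values) {
    f <- droplevels(factor(values))
    if (nlevels(f) < 2L) {
      stop("fixed factor '", col, "' has a single level after row exclusion")
    }
    dat[[col]] <- f
    dat
  }
  if ("gender" %in% spec$fixed_terms) {
    dat <- add_factor(dat, "gender", df$gender); parts <- c(parts, "gender")
  }
  if ("batch_stable" %in% spec$fixed_terms) {
    dat <- add_factor(dat, "bs", paste0(df$batch, ".", df$stable))
    parts <- c(parts, "bs")
  }
  if ("age" %in% spec$fixed_terms) {
    agecol <- paste0("age_", spec$response)
    f <- droplevels(factor(df[[agecol]]))
    # recording age may come out single-valued in small subsets; a constant
    # age carries no information, so it is dropped rather than an error
    if (nlevels(f) >= 2L) { dat$age <- f; parts <- c(parts, "age") }
  }
  if ("person" %in% spec$fixed_terms) {
    dat <- add_factor(dat, "person", df$person); parts <- c(parts, "person")
  }
  sev_scale <- 1
  if ("slope_terms" %in% spec$fixed_terms) {
    stopifnot(!is.null(sev))
    # the severity covariate enters the fixed design standardized to unit
    # root-mean-square over all records: a pure reparameterization of one
    # fit, but it keeps the REML log|X'V^-1X| term (and hence AIC/BIC)
    # comparable across plateau-threshold candidates, whose raw covariates
    # differ in both scale and affected fraction
    if (any(sev != 0)) sev_scale <- sqrt(mean(sev^2))
    if (sev_scale <= 0) sev_scale <- 1
    dat$sev <- sev / sev_scale
    parts <- c(parts, "sev")
    if ("bs" %in% names(dat)) parts <- c(parts, "sev:bs")
    if ("person" %in% names(dat)) parts <- c(parts, "sev:person")
  }
  if ("bw2_covariate" %in% spec$fixed_terms) {
    dat$bw2 <- df$bw2; parts <- c(parts, "bw2")
  }
  fml <- stats::as.formula(paste("~", paste(c("1", parts), collapse = " + ")))
  X <- stats::model.matrix(fml, dat)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("fixed design is rank deficient; confounded columns: ",
         paste(bad, collapse = ", "))
  }
  avg_deriv <- NULL
  if ("slope_terms" %in% spec$fixed_terms) {
    d1 <- dat; d1$sev <- 1
    d0 <- dat; d0$sev <- 0
    # derivative of the fixed part with respect to the natural (unscaled)
    # severity, averaged over records
    avg_deriv <- colMeans(stats::model.matrix(fml, d1) -
                          stats::model.matrix(fml, d0)) / sev_scale
  }
  if (nzchar(prefix)) {
    colnames(X) <- paste0(prefix, colnames(X))
    if (!is.null(avg_deriv)) names(avg_deriv) <- colnames(X)
  }
  list(X = methods::as(X, "CsparseMatrix"), avg_deriv = avg_deriv)
}

make_random_term <- function(r, df, ped, sev, n) {
  design <- switch(r$design,
    intercept = matrix(1, n, 1, dimnames = list(NULL, "intercept")),
    reaction_norm = {
      stopifnot(!is.null(sev))
      cbind(intercept = rep(1, n), slope = sev)
    },
    stop("unknown random design: ", r$design))
  build_term(name = r$name, structure = r$structure,
             id_values = df[[r$id]], design = design, ped = ped)
}

#' Assemble a generic mixed-model design
#'
#' Lower-level companion to [build_design()] for models outside the
#' pre-canned study specifications (e.g. a plain sire model on a balanced
#' design). Takes the response, a fixed design matrix, and a list of random
#' terms given by grouping vectors.
#'
#' @param y numeric response vector.
#' @param X fixed design matrix (defaults to an intercept column); must be
#'   full rank.
#' @param random list of terms: each a list with `name`, `id` (grouping
#'   vector of length `n`), `structure` (`"iid"` or `"ped"`), and optional
#'   `design` (n x k matrix; defaults to an intercept column).
#' @param ped pedigree, required for `"ped"` terms.
#' @param resid_class integer residual-class vector (default one class).
#' @return an `mm_design` object for [reml_fit()].
#' @export
mixed_design <- function(y, X = NULL, random, ped = NULL,
                         resid_class = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("fixed design is rank deficient")
  if (is.null(resid_class)) resid_class <- rep(1L, n)
  cls <- match(resid_class, sort(unique(resid_class)))
  labels <- paste0("class", sort(unique(resid_class)))
  if (length(labels) == 1L) labels <- "var"
  terms <- lapply(random, function(r) {
    design <- r$design
    if (is.null(design)) design <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    if (is.null(colnames(design))) {
      colnames(design) <- if (ncol(design) == 1L) "intercept"
        else paste0("c", seq_len(ncol(design)))
    }
    build_term(name = r$name, structure = r$structure %||% "iid",
               id_values = r$id, design = design, ped = ped)
  })
  names(terms) <- vapply(terms, `[[`, character(1), "name")
  resid <- list(type = "classes", var_class = cls, var_labels = labels,
                block_id = seq_len(n), slot = rep(1L, n), pairs = list())
  structure(list(y = y, X = methods::as(X, "CsparseMatrix"),
                 avg_deriv = NULL, n = n, terms = terms, resid = resid,
                 spec = NULL, row_animal = NULL),
            class = "mm_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared term builder: levels, incidence matrix, structure inverse
build_term <- function(name, structure, id_values, design, ped) {
  k <- ncol(design)
  if (structure == "ped") {
    levels <- ped$animal
    missing <- setdiff(unique(id_values), levels)
    if (length(missing)) {
      stop("animals with records but not in the pedigree: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    Ainv <- a_inverse(ped)
    logdet_a <- attr(Ainv, "logdet_a")
  } else {
    levels <- sort(unique(id_values))
    Ainv <- NULL
    logdet_a <- 0
  }
  q <- length(levels)
  aidx <- match(id_values, levels)
  n <- length(id_values)
  i <- rep(seq_len(n), k)
  j <- as.vector(vapply(seq_len(k), function(kk) (aidx - 1L) * k + kk,
                        integer(n)))
  x <- as.vector(design)
  Z <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, q * k))
  list(name = name, structure = structure, k = k, q = q, levels = levels,
       colnames = colnames(design), Z = Z, Ainv = Ainv, logdet_a = logdet_a)
}
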