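# REML engine: sparse mixed-model-equations likelihood with fast numeric
# refactorization, quasi-Newton maximization over log-Cholesky-transformed
# variance parameters, and BLUP/BLUE solutions at the optimum.
#
# For variance parameters theta defining G (random-term covariance, block
# A (x) G0 per term) and R (residual), the REML log-likelihood is
#   -2 logL = log|R| + log|G| + log|C| + y'Py + (n - p) log(2 pi)
# with C the mixed-model-equation coefficient matrix
#   C = W' R^-1 W + blockdiag(0, G^-1),  W = [X Z],
# and y'Py = y'R^-1 y - r' C^-1 r, r = W' R^-1 y. All quantities reduce to
# a fixed sparsity pattern whose values are linear in 1/sigma^2-type
# coefficients, so each likelihood evaluation is a vector update of the
# pattern plus one sparse Cholesky refactorization.

as_dsc_lower <- function(M) {
  M <- Matrix::forceSymmetric(M)
  if (M@uplo == "U") M <- t(M)
  M
}

dsc_keys <- function(M) {
  P <- nrow(M)
  rows <- M@i + 1L
  cols <- rep(seq_len(P), diff(M@p))
  rows + (cols - 1) * as.double(P)
}

ones_pattern <- function(M) {
  M@x[] <- 1
  M
}

#' REML fitting control
#'
#' @param rel_tol relative change in the REML log-likelihood treated as
#'   converged.
#' @param max_iter maximum optimizer iterations.
#' @export
reml_control <- function(rel_tol = 1e-12, max_iter = 300) {
  list(rel_tol = rel_tol, max_iter = max_iter)
}

# ---- engine assembly --------------------------------------------------

assemble_engine <- function(design) {
  y <- design$y
  n <- design$n
  X <- design$X
  p <- ncol(X)
  terms <- design$terms
  Zs <- lapply(terms, `[[`, "Z")
  W <- do.call(cbind, c(list(X), Zs))
  P <- ncol(W)
  offs <- p + c(0, cumsum(vapply(terms, function(t) t$q * t$k, numeric(1))))

  resid <- design$resid
  # residual blocks -> patterns of aligned record rows
  if (all(tabulate(resid$block_id) <= 1L)) {
    patterns <- lapply(sort(unique(resid$var_class)), function(cc) {
      list(m = 1L, classes = cc, rowsmat = matrix(which(resid$var_class == cc), ncol = 1L))
    })
  } else {
    ord <- order(resid$block_id, resid$slot)
    blocks <- split(ord, resid$block_id[ord])
    if (any(vapply(blocks, function(b) anyDuplicated(resid$slot[b]) > 0L, logical(1)))) {
      stop("residual blocks must have at most one record per slot")
    }
    key <- vapply(blocks, function(b) paste(resid$var_class[b], collapse = "|"),
                  character(1))
    patterns <- lapply(split(blocks, key), function(bl) {
      rowsmat <- do.call(rbind, lapply(bl, identity))
      list(m = ncol(rowsmat), classes = resid$var_class[rowsmat[1L, ]],
           rowsmat = rowsmat)
    })
    names(patterns) <- NULL
  }

  pieces <- list()
  for (pi in seq_along(patterns)) {
    pat <- patterns[[pi]]
    for (a in seq_len(pat$m)) {
      for (b in a:pat$m) {
        ra <- pat$rowsmat[, a]
        rb <- pat$rowsmat[, b]
        if (a == b) {
          S <- as_dsc_lower(Matrix::crossprod(W[ra, , drop = FALSE]))
          bvec <- as.numeric(Matrix::crossprod(W[ra, , drop = FALSE], y[ra]))
          yy <- sum(y[ra]^2)
        } else {
          M <- Matrix::crossprod(W[ra, , drop = FALSE], W[rb, , drop = FALSE])
          S <- as_dsc_lower(M + t(M))
          bvec <- as.numeric(Matrix::crossprod(W[ra, , drop = FALSE], y[rb])) +
            as.numeric(Matrix::crossprod(W[rb, , drop = FALSE], y[ra]))
          yy <- 2 * sum(y[ra] * y[rb])
        }
        pieces[[length(pieces) + 1L]] <-
          list(pattern = pi, a = a, b = b, S = S, bvec = bvec, yy = yy)
      }
    }
  }

  # G-inverse kron expansions per term
  gparts <- vector("list", length(terms))
  for (ti in seq_along(terms)) {
    tm <- terms[[ti]]
    k <- tm$k
    off <- offs[ti]
    if (tm$structure == "ped") {
      A <- as_dsc_lower(tm$Ainv)
      ai <- A@i + 1L
      aj <- rep(seq_len(tm$q), diff(A@p))
      av <- A@x
    } else {
      ai <- aj <- seq_len(tm$q)
      av <- rep(1, tm$q)
    }
    ne <- length(ai)
    rg <- cg <- aval <- krv <- kcv <- vector("list", k * k)
    ii <- 0L
    for (kr in seq_len(k)) {
      for (kc in seq_len(k)) {
        r <- off + (ai - 1L) * k + kr
        c_ <- off + (aj - 1L) * k + kc
        keep <- r >= c_
        ii <- ii + 1L
        rg[[ii]] <- r[keep]; cg[[ii]] <- c_[keep]
        aval[[ii]] <- av[keep]
        krv[[ii]] <- rep.int(kr, sum(keep)); kcv[[ii]] <- rep.int(kc, sum(keep))
      }
    }
    gparts[[ti]] <- list(r = unlist(rg), c = unlist(cg), aval = unlist(aval),
                         kr = unlist(krv), kc = unlist(kcv),
                         k = k, q = tm$q, logdet_a = tm$logdet_a)
  }

  union_parts <- c(lapply(pieces, function(pc) ones_pattern(pc$S)),
                   lapply(gparts, function(gp) {
                     as_dsc_lower(Matrix::forceSymmetric(
                       Matrix::sparseMatrix(i = gp$r, j = gp$c, x = 1,
                                            dims = c(P, P)), uplo = "L"))
                   }))
  U <- Reduce(`+`, union_parts)
  U <- as_dsc_lower(U)
  keysU <- dsc_keys(U)

  for (i in seq_along(pieces)) {
    keys <- dsc_keys(pieces[[i]]$S)
    pieces[[i]]$idx <- match(keys, keysU)
    pieces[[i]]$sx <- pieces[[i]]$S@x
    pieces[[i]]$S <- NULL
  }
  for (i in seq_along(gparts)) {
    keys <- gparts[[i]]$r + (gparts[[i]]$c - 1) * as.double(P)
    gparts[[i]]$idx <- match(keys, keysU)
  }

  nblocks <- vapply(patterns, function(pat) nrow(pat$rowsmat), numeric(1))
  env <- new.env(parent = emptyenv())
  env$fac <- NULL
  list(y = y, n = n, p = p, P = P, W = W, U = U, nnz = length(U@x),
       pieces = pieces, gparts = gparts, patterns = patterns,
       nblocks = nblocks, resid = resid, terms = terms, offs = offs,
       xnames = colnames(X), cache = env)
}

# residual natural parameters psi = (variances per class, correlations per
# slot pair) -> per-pattern residual matrices
resid_matrices <- function(engine, psi) {
  nv <- length(engine$resid$var_labels)
  v <- psi[seq_len(nv)]
  rho <- if (length(engine$resid$pairs)) psi[nv + seq_along(engine$resid$pairs)] else numeric(0)
  lapply(engine$patterns, function(pat) {
    m <- pat$m
    R <- diag(v[pat$classes], m)
    if (m > 1L && length(rho)) {
      for (a in seq_len(m - 1L)) {
        for (b in (a + 1L):m) {
          R[a, b] <- R[b, a] <- rho[1L] * sqrt(v[pat$classes[a]] * v[pat$classes[b]])
        }
      }
    }
    R
  })
}

eval_reml <- function(engine, G0s, psi, solve_system = FALSE) {
  Rmats <- resid_matrices(engine, psi)
  rinvs <- vector("list", length(Rmats))
  logdet_r <- 0
  for (i in seq_along(Rmats)) {
    dt <- det(Rmats[[i]])
    if (!is.finite(dt) || dt <= 0) return(NULL)
    rinvs[[i]] <- solve(Rmats[[i]])
    logdet_r <- logdet_r + engine$nblocks[i] * log(dt)
  }

  xs <- numeric(engine$nnz)
  rhs <- numeric(engine$P)
  yry <- 0
  for (pc in engine$pieces) {
    coef <- rinvs[[pc$pattern]][pc$a, pc$b]
    if (coef != 0) {
      xs[pc$idx] <- xs[pc$idx] + coef * pc$sx
      rhs <- rhs + coef * pc$bvec
      yry <- yry + coef * pc$yy
    }
  }

  logdet_g <- 0
  for (ti in seq_along(engine$gparts)) {
    gp <- engine$gparts[[ti]]
    G0 <- G0s[[ti]]
    ch <- tryCatch(chol(G0), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    G0inv <- chol2inv(ch)
    logdet_g <- logdet_g + gp$k * gp$logdet_a + gp$q * 2 * sum(log(diag(ch)))
    xs[gp$idx] <- xs[gp$idx] + gp$aval * G0inv[cbind(gp$kr, gp$kc)]
  }

  C <- engine$U
  C@x <- xs
  fac <- tryCatch({
    if (is.null(engine$cache$fac)) {
      engine$cache$fac <- Matrix::Cholesky(C, LDL = FALSE, super = NA)
      engine$cache$fac
    } else {
      Matrix::update(engine$cache$fac, C)
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fac)) return(NULL)
  logdet_c <- 2 * as.numeric(Matrix::determinant(fac, logarithm = TRUE,
                                                 sqrt = TRUE)$modulus)
  sol <- as.numeric(Matrix::solve(fac, rhs, system = "A"))
  ypy <- yry - sum(rhs * sol)
  m2ll <- logdet_r + logdet_g + logdet_c + ypy +
    (engine$n - engine$p) * log(2 * pi)
  if (!is.finite(m2ll)) return(NULL)
  out <- list(m2ll = m2ll, logL = -0.5 * m2ll)
  if (solve_system) out$sol <- sol
  out
}

# ---- parameterization -------------------------------------------------

# theta: unconstrained optimizer scale (log variances, log-Cholesky blocks,
# atanh correlations). phi: natural named components used for reporting,
# standard errors and delta-method functions.

build_param_map <- function(design, engine) {
  terms <- design$terms
  resid <- design$resid
  y <- design$y

  # scale heuristics from the data (never from generating values)
  vtot <- max(stats::var(y), 1e-10)
  term_scales <- lapply(terms, function(tm) {
    k <- tm$k
    sc <- numeric(k)
    Z <- tm$Z
    for (kk in seq_len(k)) {
      colsel <- seq(kk, tm$q * k, by = k)
      dv <- Matrix::rowSums(abs(Z[, colsel, drop = FALSE]))
      act <- which(dv > 0)
      vy <- if (length(act) > 5L) stats::var(y[act]) else vtot
      msq <- if (length(act)) {
        zz <- Z[act, colsel, drop = FALSE]
        sum(zz@x^2) / length(act)
      } else 1
      sc[kk] <- max(0.3 * vy / max(msq, 1e-10), 1e-10)
    }
    sc
  })
  nv <- length(resid$var_labels)
  resid_scale <- vapply(seq_len(nv), function(cc) {
    sel <- resid$var_class == cc
    vy <- if (sum(sel) > 5L) stats::var(y[sel]) else vtot
    max(0.5 * vy, 1e-10)
  }, numeric(1))
  n_rho <- length(resid$pairs)

  term_npar <- vapply(terms, function(tm) as.integer(tm$k * (tm$k + 1L) / 2L),
                      integer(1))
  n_theta <- sum(term_npar) + nv + n_rho

  slice <- function(sizes) {
    ends <- cumsum(sizes)
    mapply(function(s, e) seq.int(s, e),
           c(1, utils::head(ends, -1) + 1), ends, SIMPLIFY = FALSE)
  }
  sl <- slice(c(term_npar, nv, if (n_rho) n_rho else NULL))
  term_sl <- sl[seq_along(terms)]
  var_sl <- sl[[length(terms) + 1L]]
  rho_sl <- if (n_rho) sl[[length(terms) + 2L]] else integer(0)

  lower_index <- function(k) which(lower.tri(matrix(0, k, k), diag = TRUE))

  theta_to_natural <- function(theta) {
    G0s <- vector("list", length(terms))
    for (ti in seq_along(terms)) {
      k <- terms[[ti]]$k
      L <- matrix(0, k, k)
      vals <- theta[term_sl[[ti]]]
      L[lower_index(k)] <- vals
      diag(L) <- exp(diag(L))
      G0s[[ti]] <- L %*% t(L)
    }
    psi <- c(exp(theta[var_sl]),
             if (n_rho) tanh(theta[rho_sl]) else numeric(0))
    list(G0s = G0s, psi = psi)
  }

  natural_to_theta <- function(G0s, psi) {
    th <- numeric(0)
    for (ti in seq_along(terms)) {
      k <- terms[[ti]]$k
      G0 <- G0s[[ti]]
      L <- t(chol(G0 + diag(1e-12 * max(diag(G0), 1e-12), k)))
      d <- diag(L)
      diag(L) <- log(d)
      th <- c(th, L[lower_index(k)])
    }
    th <- c(th, log(pmax(psi[seq_len(nv)], 1e-12)),
            if (n_rho) atanh(pmin(pmax(psi[nv + seq_len(n_rho)], -0.99), 0.99)))
    th
  }

  phi_names <- character(0)
  for (ti in seq_along(terms)) {
    tm <- terms[[ti]]
    cn <- tm$colnames
    nms <- character(0)
    for (cc in seq_len(tm$k)) {
      for (rr in cc:tm$k) {
        nms <- c(nms, if (rr == cc) paste0(tm$name, ".var_", cn[cc])
                 else paste0(tm$name, ".cov_", cn[cc], "_", cn[rr]))
      }
    }
    # single-column terms read better without the design-column suffix
    if (tm$k == 1L) nms <- paste0(tm$name, ".var")
    phi_names <- c(phi_names, nms)
  }
  phi_names <- c(phi_names, paste0("residual.", resid$var_labels),
                 if (n_rho) paste0("residual.rho", seq_len(n_rho)) else character(0))

  natural_to_phi <- function(G0s, psi) {
    phi <- numeric(0)
    for (ti in seq_along(terms)) {
      k <- terms[[ti]]$k
      phi <- c(phi, G0s[[ti]][lower_index(k)])
    }
    stats::setNames(c(phi, psi), phi_names)
  }

  phi_to_natural <- function(phi) {
    G0s <- vector("list", length(terms))
    pos <- 0L
    for (ti in seq_along(terms)) {
      k <- terms[[ti]]$k
      np <- k * (k + 1L) / 2L
      G0 <- matrix(0, k, k)
      G0[lower_index(k)] <- phi[pos + seq_len(np)]
      G0 <- G0 + t(G0) - diag(diag(G0), k)
      G0s[[ti]] <- G0
      pos <- pos + np
    }
    list(G0s = G0s, psi = unname(phi[pos + seq_len(nv + n_rho)]))
  }

  start_theta <- function() {
    G0s <- lapply(seq_along(terms), function(ti) {
      diag(term_scales[[ti]], terms[[ti]]$k)
    })
    psi <- c(resid_scale, rep(0, n_rho))
    natural_to_theta(G0s, psi)
  }

  bounds <- function() {
    lo <- numeric(0); hi <- numeric(0)
    for (ti in seq_along(terms)) {
      k <- terms[[ti]]$k
      sc <- term_scales[[ti]]
      l <- matrix(-Inf, k, k); h <- matrix(Inf, k, k)
      for (cc in seq_len(k)) {
        l[cc, cc] <- 0.5 * log(sc[cc]) - 10
        h[cc, cc] <- 0.5 * log(sc[cc]) + 7
        if (cc < k) {
          l[(cc + 1):k, cc] <- -50 * sqrt(sc[(cc + 1):k])
          h[(cc + 1):k, cc] <- 50 * sqrt(sc[(cc + 1):k])
        }
      }
      sel <- lower_index(k)
      lo <- c(lo, l[sel]); hi <- c(hi, h[sel])
    }
    lo <- c(lo, log(resid_scale) - 18, rep(-3, n_rho))
    hi <- c(hi, log(resid_scale) + 10, rep(3, n_rho))
    list(lower = lo, upper = hi)
  }

  list(n_theta = n_theta, theta_to_natural = theta_to_natural,
       natural_to_theta = natural_to_theta, phi_names = phi_names,
       natural_to_phi = natural_to_phi, phi_to_natural = phi_to_natural,
       start_theta = start_theta, bounds = bounds,
       var_phi = grepl("\\.var", phi_names) | grepl("residual\\.(?!rho)",
                                                    phi_names, perl = TRUE))
}

# ---- fitting ----------------------------------------------------------

#' Fit an animal model by REML
#'
#' Maximizes the restricted likelihood of the mixed model described by a
#' [model_spec()] (or a pre-assembled design) over the variance parameters,
#' then solves the mixed-model equations at the optimum for BLUE fixed
#' effects and BLUP random effects (estimated breeding values). Components
#' are parameterized through log-Cholesky factors, so every iterate is
#' positive semidefinite by construction.
#'
#' @param spec a [model_spec()] or an `mm_design` from [build_design()].
#' @param pheno phenotype table (ignored when `spec` is a design).
#' @param ped pedigree (ignored when `spec` is a design).
#' @param start optional start values: the `theta` vector of a previous fit
#'   on a model with the same parameter layout.
#' @param se `"hessian"` for standard errors of all components via the
#'   observed-information (numerical curvature) matrix, `"none"` to skip.
#' @param control a [reml_control()] list.
#' @return object of class `reml_fit` with elements `components` (named
#'   estimates), `se`, `vcov_components`, `logL`, `aic`, `bic`,
#'   `n_records`, `n_parameters`, `converged`, `boundary`, `fixed`,
#'   `ranef` (list of per-term solution matrices), `theta`.
#' @export
reml_fit <- function(spec, pheno = NULL, ped = NULL, start = NULL,
                     se = c("hessian", "none"), control = reml_control()) {
  se <- match.arg(se)
  design <- if (inherits(spec, "mm_design")) spec else
    build_design(spec, pheno, ped)
  engine <- assemble_engine(design)
  map <- build_param_map(design, engine)

  obj <- function(theta) {
    nat <- map$theta_to_natural(theta)
    ev <- eval_reml(engine, nat$G0s, nat$psi)
    if (is.null(ev)) return(1e10)
    0.5 * ev$m2ll
  }
  th0 <- if (!is.null(start)) {
    if (length(start) != map$n_theta) {
      stop("start values have wrong length (", length(start), " vs ",
           map$n_theta, ")")
    }
    start
  } else map$start_theta()
  bd <- map$bounds()
  ctl <- list(iter.max = control$max_iter, eval.max = control$max_iter * 20,
              rel.tol = control$rel_tol)
  opt <- stats::nlminb(th0, obj, lower = bd$lower, upper = bd$upper,
                       control = ctl)
  # a warm restart resets the trust region: it sharpens parameter accuracy
  # near smooth optima and distinguishes genuinely stuck runs from the
  # "singular/false convergence" labels nlminb gives near-flat REML optima
  opt2 <- stats::nlminb(opt$par, obj, lower = bd$lower, upper = bd$upper,
                        control = ctl)
  improved <- (opt$objective - opt2$objective) >
    1e-6 * (abs(opt$objective) + 1)
  if (opt2$objective <= opt$objective) opt <- opt2
  converged <- opt$convergence == 0 || opt2$convergence == 0 || !improved
  converged <- converged && is.finite(opt$objective) && opt$objective < 1e9

  # quasi-Newton accuracy bottoms out at the forward-difference noise floor
  # (~1e-5 in the parameters); for low-dimensional models a central-
  # difference Newton polish is cheap and pushes the optimum to oracle
  # precision (balanced-design estimates then match ANOVA closed forms)
  if (converged && map$n_theta <= 4) {
    for (it in 1:3) {
      ng <- newton_step(obj, opt$par, bd$lower, bd$upper)
      if (is.null(ng) || ng$objective > opt$objective) break
      moved <- max(abs(ng$par - opt$par))
      opt$par <- ng$par
      opt$objective <- ng$objective
      if (moved < 1e-10) break
    }
  }

  nat <- map$theta_to_natural(opt$par)
  ev <- eval_reml(engine, nat$G0s, nat$psi, solve_system = TRUE)
  if (is.null(ev)) stop("likelihood evaluation failed at the optimum")
  phi <- map$natural_to_phi(nat$G0s, nat$psi)
  k_par <- map$n_theta
  n <- engine$n
  logL <- ev$logL

  # boundary: any log-variance within numerical reach of its lower bound
  at_lower <- abs(opt$par - bd$lower) < 1e-4
  boundary <- any(at_lower)

  sol <- ev$sol
  fixed <- stats::setNames(sol[seq_len(engine$p)], engine$xnames)
  ranef <- list()
  for (ti in seq_along(engine$terms)) {
    tm <- engine$terms[[ti]]
    v <- sol[engine$offs[ti] + seq_len(tm$q * tm$k)]
    m <- matrix(v, nrow = tm$q, ncol = tm$k, byrow = TRUE,
                dimnames = list(tm$levels, tm$colnames))
    ranef[[tm$name]] <- m
  }

  fit <- structure(list(
    components = phi, se = rep(NA_real_, length(phi)),
    vcov_components = NULL, logL = logL,
    aic = -2 * logL + 2 * k_par, bic = -2 * logL + k_par * log(n),
    n_records = n, n_parameters = k_par, converged = converged,
    boundary = boundary, fixed = fixed, ranef = ranef,
    avg_deriv = design$avg_deriv, theta = opt$par,
    spec = design$spec, resid_labels = engine$resid$var_labels,
    map = map, engine = engine), class = "reml_fit")
  names(fit$se) <- names(phi)

  if (se == "hessian" && converged) {
    H <- tryCatch(phi_hessian(engine, map, phi), error = function(e) NULL)
    if (!is.null(H)) {
      # components at a (co)variance boundary make the likelihood
      # one-sided there: their curvature rows come back NA and their SEs
      # stay unavailable, while the clean submatrix is inverted normally
      ok <- is.finite(diag(H))
      if (any(ok) && all(is.finite(H[ok, ok]))) {
        Vsub <- tryCatch(solve(H[ok, ok, drop = FALSE]),
                         error = function(e) NULL)
        if (!is.null(Vsub) && all(is.finite(diag(Vsub))) &&
            all(diag(Vsub) > 0)) {
          V <- matrix(NA_real_, length(phi), length(phi),
                      dimnames = list(names(phi), names(phi)))
          V[ok, ok] <- Vsub
          fit$vcov_components <- V
          fit$se[ok] <- sqrt(diag(Vsub))
        }
      }
    }
  }
  fit
}

# one safeguarded Newton step from central-difference gradient and Hessian
newton_step <- function(obj, par, lower, upper, h_rel = 1e-5) {
  np <- length(par)
  h <- pmax(abs(par), 0.1) * h_rel
  g <- numeric(np)
  H <- matrix(0, np, np)
  f0 <- obj(par)
  fp <- fm <- numeric(np)
  for (i in seq_len(np)) {
    ei <- numeric(np); ei[i] <- h[i]
    fp[i] <- obj(par + ei)
    fm[i] <- obj(par - ei)
    g[i] <- (fp[i] - fm[i]) / (2 * h[i])
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  if (np > 1L) {
    for (i in 2:np) {
      for (j in seq_len(i - 1L)) {
        ei <- numeric(np); ei[i] <- h[i]
        ej <- numeric(np); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (obj(par + ei + ej) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] +
           obj(par - ei - ej)) / (2 * h[i] * h[j])
      }
    }
  }
  step <- tryCatch(-solve(H, g), error = function(e) NULL)
  if (is.null(step) || !all(is.finite(step))) return(NULL)
  newpar <- pmin(pmax(par + step, lower), upper)
  fnew <- obj(newpar)
  if (!is.finite(fnew)) return(NULL)
  list(par = newpar, objective = fnew)
}

neg_ll_phi <- function(engine, map, phi) {
  nat <- map$phi_to_natural(phi)
  ev <- eval_reml(engine, nat$G0s, nat$psi)
  if (is.null(ev)) return(NA_real_)
  0.5 * ev$m2ll
}

phi_hessian <- function(engine, map, phi, rel_h = 1e-4) {
  f <- function(x) neg_ll_phi(engine, map, x)
  np <- length(phi)
  h <- pmax(abs(phi), 1e-3) * rel_h
  H <- matrix(NA_real_, np, np)
  f0 <- f(phi)
  for (i in seq_len(np)) {
    ei <- numeric(np); ei[i] <- h[i]
    H[i, i] <- (f(phi + ei) - 2 * f0 + f(phi - ei)) / h[i]^2
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        ej <- numeric(np); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (f(phi + ei + ej) - f(phi + ei - ej) -
           f(phi - ei + ej) + f(phi - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  dimnames(H) <- list(names(phi), names(phi))
  H
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", x$n_records, "records,", x$n_parameters,
      "variance parameters\n")
  cat("logL =", format(x$logL, digits = 8),
      " AIC =", format(x$aic, digits = 8),
      " BIC =", format(x$bic, digits = 8),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  tab <- data.frame(estimate = x$components, se = x$se)
  print(format(tab, digits = 4))
  invisible(x)
}

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logL, df = object$n_parameters, class = "logLik")
}

#' @export
vcov.reml_fit <- function(object, ...) object$vcov_components

#' Information criteria of a REML fit
#'
#' `AIC = -2 logL + 2 k` and `BIC = -2 logL + k log(n)` with `k` the number
#' of variance parameters and `n` the number of records, computed from the
#' REML log-likelihood.
#'
#' @param fit a [reml_fit()] result.
#' @return named vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit) {
  c(aic = -2 * fit$logL + 2 * fit$n_parameters,
    bic = -2 * fit$logL + fit$n_parameters * log(fit$n_records))
}

#' Delta-method standard error of a function of components
#'
#' First-order delta method through a user function of the named variance
#' components, using the observed-information covariance matrix of the fit.
#'
#' @param fit a [reml_fit()] result fitted with `se = "hessian"`.
#' @param f function taking the named component vector, returning a scalar
#'   (e.g. a heritability or a correlation).
#' @return list with `value`, `se` (NA with `available = FALSE` when the
#'   curvature matrix is unavailable or singular).
#' @export
delta_se <- function(fit, f) {
  stopifnot(inherits(fit, "reml_fit"))
  phi <- fit$components
  value <- f(phi)
  V <- fit$vcov_components
  if (is.null(V)) {
    return(list(value = value, se = NA_real_, available = FALSE))
  }
  np <- length(phi)
  h <- pmax(abs(phi), 1e-3) * 1e-5
  g <- numeric(np)
  for (i in seq_len(np)) {
    ei <- numeric(np); ei[i] <- h[i]
    g[i] <- (f(phi + ei) - f(phi - ei)) / (2 * h[i])
  }
  idx <- which(abs(g) > 0)
  if (!length(idx)) return(list(value = value, se = 0, available = TRUE))
  Vsub <- V[idx, idx, drop = FALSE]
  if (any(!is.finite(Vsub))) {
    return(list(value = value, se = NA_real_, available = FALSE))
  }
  s2 <- drop(t(g[idx]) %*% Vsub %*% g[idx])
  if (!is.finite(s2) || s2 < 0) {
    return(list(value = value, se = NA_real_, available = FALSE))
  }
  list(value = value, se = sqrt(s2), available = TRUE)
}

#' Record-averaged fixed population slope
#'
#' For tolerance models with fixed slope interaction terms, the population
#' mean slope is the derivative of the fixed part with respect to severity
#' averaged over the fitted records (reference-level coding makes the bare
#' severity coefficient refer to the reference batch/stable/cutter cell
#' only).
#'
#' @param fit a [reml_fit()] of a model with fixed slope terms.
#' @return scalar population slope (trait units per percent severity).
#' @export
population_slope <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (is.null(fit$avg_deriv)) stop("model has no fixed slope terms")
  sum(fit$avg_deriv * fit$fixed[names(fit$avg_deriv)])
}
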