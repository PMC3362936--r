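#' Pedigree objects
#'
#' A pedigree is a topologically sorted table of animal/sire/dam triplets
#' with per-animal inbreeding coefficients. Unknown parents are treated as
#' unrelated founders. The additive (numerator) relationship matrix A is
#' implied by the triplets; its sparse inverse is what the animal models
#' actually use.
#'
#' @param animal,sire,dam character vectors of identifiers. Unknown parents
#'   may be coded as `NA`, `""` or `"0"`.
#' @return An object of class `pedigree`: a data frame with columns
#'   `animal`, `sire`, `dam` (character, `NA` for unknown), ordered so that
#'   parents precede offspring, plus a numeric column `f` of inbreeding
#'   coefficients. Attribute `d` holds the Mendelian-sampling variance of
#'   each animal (used for the sparse A-inverse and its log-determinant).
#' @examples
#' ped <- new_pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' ped$f
#' @export
new_pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- normalize_parent(sire)
  dam <- normalize_parent(dam)
  if (anyNA(animal) || any(animal == "")) {
    stop("animal ids must be non-missing")
  }
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  self <- which(!is.na(sire) & sire == animal | !is.na(dam) & dam == animal)
  if (length(self)) {
    stop("animal(s) recorded as their own parent: ",
         paste(animal[self], collapse = ", "))
  }
  ord <- topological_order(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  # parents referenced but absent from the animal column become founders
  known <- ped$animal
  ped$sire[!is.na(ped$sire) & !(ped$sire %in% known)] <- NA
  ped$dam[!is.na(ped$dam) & !(ped$dam %in% known)] <- NA
  fd <- inbreeding_ml(ped)
  ped$f <- fd$f
  attr(ped, "d") <- fd$d
  class(ped) <- c("pedigree", "data.frame")
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0" | toupper(x) == "NA"] <- NA_character_
  x
}

# Kahn-style topological sort; cycles reported with the offending ids.
topological_order <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), NA_integer_, unname(idx[sire]))
  di <- ifelse(is.na(dam), NA_integer_, unname(idx[dam]))
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    # take the earliest remaining record to keep the order stable
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(animal[setdiff(idx, out)], collapse = ", "))
  }
  out
}

#' Read a pedigree file
#'
#' Reads a 3-column delimited text file (animal, sire, dam). The delimiter
#' (comma or tab) is autodetected and a header line is optional. Unknown
#' parents may be coded `0`, empty, or `NA`.
#'
#' @param path path to the pedigree file.
#' @return a [new_pedigree()] object, topologically sorted.
#' @export
read_pedigree <- function(path) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- any(tolower(trimws(first)) %in% c("animal", "id", "sire", "dam"))
  tab <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", strip.white = TRUE,
                           na.strings = c("NA", ""))
  if (ncol(tab) < 3L) stop("pedigree file must have 3 columns (animal, sire, dam)")
  new_pedigree(tab[[1]], tab[[2]], tab[[3]])
}

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x), "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders, max F =",
      format(max(x$f), digits = 4), "\n")
  invisible(x)
}

# Memoized tabular-method relationship closure over integer parent indices
# (0 = unknown). Pairs are cached, so repeated parent combinations (the
# common case in sire-dam designs) cost one evaluation.
ped_kinship_fun <- function(si, di) {
  memo <- new.env(parent = emptyenv())
  a <- function(p, q) {
    if (p == 0L || q == 0L) return(0)
    if (p < q) { tmp <- p; p <- q; q <- tmp }
    key <- paste0(p, ":", q)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (p == q) {
      1 + 0.5 * a(si[p], di[p])
    } else {
      # p is the later-born animal in topological order
      0.5 * (a(si[p], q) + a(di[p], q))
    }
    memo[[key]] <- v
    v
  }
  a
}

# Inbreeding F_i = 0.5 * a(sire_i, dam_i), founders 0, plus the
# Mendelian-sampling variances d_i used by Henderson's A-inverse rules.
inbreeding_ml <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire]))
  di <- ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
  a <- ped_kinship_fun(si, di)
  f <- numeric(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; dd <- di[i]
    f[i] <- if (s > 0L && dd > 0L) 0.5 * a(s, dd) else 0
    fs <- if (s > 0L) f[s] else -1
    fd <- if (dd > 0L) f[dd] else -1
    d[i] <- 0.5 - 0.25 * (fs + fd)
  }
  list(f = f, d = d)
}

#' Inbreeding coefficients
#'
#' @param ped a [new_pedigree()] object.
#' @return named numeric vector of inbreeding coefficients F in `[0, 1)`.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  stats::setNames(ped$f, ped$animal)
}

#' Additive relationship between two animals
#'
#' Recursive tabular-method numerator relationship. Intended for small
#' pedigrees and as an independent oracle for the sparse A-inverse;
#' quadratic-time in pedigree depth.
#'
#' @param ped a pedigree object.
#' @param i,j animal identifiers.
#' @return the additive relationship `a_ij`; `a_ii = 1 + F_i`.
#' @export
relationship <- function(ped, i, j) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  if (!(i %in% ped$animal)) stop("unknown animal id: ", i)
  if (!(j %in% ped$animal)) stop("unknown animal id: ", j)
  si <- ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire]))
  di <- ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
  a <- ped_kinship_fun(si, di)
  a(unname(idx[i]), unname(idx[j]))
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Builds the full A matrix by the recursive tabular method. Quadratic in
#' pedigree size; meant for validation and small pedigrees, not for the
#' mixed-model equations (those use [a_inverse()]).
#'
#' @param ped a pedigree object.
#' @return dense symmetric matrix with dimnames the animal ids.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire]))
  di <- ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (p in seq_len(n)) {
    for (q in seq_len(p)) {
      v <- if (p == q) {
        1 + 0.5 * (if (si[p] > 0L && di[p] > 0L) A[si[p], di[p]] else 0)
      } else {
        0.5 * ((if (si[p] > 0L) A[si[p], q] else 0) +
               (if (di[p] > 0L) A[di[p], q] else 0))
      }
      A[p, q] <- v
      A[q, p] <- v
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with the inbreeding adjustment: each animal contributes
#' 1/d_i to its own diagonal and -1/(2 d_i), 1/(4 d_i) terms to parent
#' entries, where d_i = 0.5 - 0.25 (F_s + F_d) is its Mendelian-sampling
#' variance (3/4 - F_known/4 with one parent known, 1 with none).
#'
#' @param ped a pedigree object.
#' @return sparse symmetric matrix (class `dsCMatrix`) with dimnames the
#'   animal ids and attribute `logdet_a`, the log-determinant of A itself
#'   (`sum(log d_i)`).
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire]))
  di <- ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
  d <- attr(ped, "d")
  alpha <- 1 / d
  ii <- jj <- xx <- vector("list", n)
  for (i in seq_len(n)) {
    par <- c(si[i], di[i])
    par <- par[par > 0L]
    r <- c(i, par, rep(i, length(par)), if (length(par) == 2L) par[1] else integer(0))
    c_ <- c(i, par, par, if (length(par) == 2L) par[2] else integer(0))
    v <- c(alpha[i], rep(0.25 * alpha[i], length(par)),
           rep(-0.5 * alpha[i], length(par)),
           if (length(par) == 2L) 0.25 * alpha[i] else numeric(0))
    # mirror the cross-parent term so accumulation stays symmetric
    if (length(par) == 2L) {
      r <- c(r, par[2]); c_ <- c(c_, par[1]); v <- c(v, 0.25 * alpha[i])
    }
    if (length(par)) {
      r <- c(r, par); c_ <- c(c_, rep(i, length(par)))
      v <- c(v, rep(-0.5 * alpha[i], length(par)))
    }
    ii[[i]] <- r; jj[[i]] <- c_; xx[[i]] <- v
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n), dimnames = list(ped$animal, ped$animal))
  M <- Matrix::forceSymmetric(Matrix::drop0(M, tol = 0), uplo = "L")
  attr(M, "logdet_a") <- sum(log(d))
  M
}
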