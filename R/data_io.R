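#' Read a phenotype table
#'
#' Reads a delimited text file (comma or tab autodetected) with one row per
#' bird. The expected columns are `animal`, `sire`, `dam`, `gender`,
#' `batch`, `stable`, `age_bw2`, `age_bw7`, `age_ratio`, `person`, `bw2`,
#' `bw7`, `ratio`; other names can be mapped via `col_map`. Trait cells may
#' be empty or `NA` (e.g. birds that died before the 7-week weighing).
#'
#' @param path path to the file.
#' @param pedigree optional pedigree; when given, every sire and dam
#'   referenced by the table must appear in it.
#' @param col_map optional named character vector mapping schema names to
#'   file column names, e.g. `c(animal = "id", bw2 = "weight2")`.
#' @return a `phenotype_table` data frame.
#' @export
read_phenotypes <- function(path, pedigree = NULL, col_map = NULL) {
  sep <- detect_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           na.strings = c("NA", ""))
  if (!is.null(col_map)) {
    for (schema in names(col_map)) {
      if (!col_map[[schema]] %in% names(tab)) {
        stop("mapped column '", col_map[[schema]], "' not in file")
      }
      names(tab)[names(tab) == col_map[[schema]]] <- schema
    }
  }
  as_phenotypes(tab, pedigree)
}

#' Validate a data frame of phenotype records
#'
#' @param tab data frame with the schema columns.
#' @param pedigree optional pedigree for parent checks.
#' @return a `phenotype_table` data frame with trait availability counts in
#'   attribute `trait_counts`.
#' @export
as_phenotypes <- function(tab, pedigree = NULL) {
  required <- c("animal", "sire", "dam", "gender", "batch", "stable",
                "age_bw2", "age_bw7", "age_ratio", "person",
                "bw2", "bw7", "ratio")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("phenotype table lacks columns: ", paste(missing, collapse = ", "))
  }
  tab <- tab[required]
  for (col in c("animal", "sire", "dam", "gender")) {
    tab[[col]] <- as.character(tab[[col]])
  }
  for (col in c("bw2", "bw7", "ratio")) tab[[col]] <- as.numeric(tab[[col]])
  bad <- which(!is.na(tab$ratio) & (tab$ratio <= 0 | tab$ratio >= 100))
  if (length(bad)) {
    stop("heart ratio out of (0, 100) in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ages <- c("age_bw2", "age_bw7", "age_ratio")
  for (col in ages) {
    if (any(!is.na(tab[[col]]) & tab[[col]] <= 0)) {
      stop("non-positive recording age in column ", col)
    }
  }
  if (!is.null(pedigree)) {
    stopifnot(inherits(pedigree, "pedigree"))
    parents <- unique(c(tab$sire, tab$dam))
    parents <- parents[!is.na(parents)]
    unknown <- setdiff(parents, pedigree$animal)
    if (length(unknown)) {
      stop("parents referenced by phenotypes but missing from the pedigree: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  attr(tab, "trait_counts") <- c(bw2 = sum(!is.na(tab$bw2)),
                                 bw7 = sum(!is.na(tab$bw7)),
                                 ratio = sum(!is.na(tab$ratio)))
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' @export
print.phenotype_table <- function(x, ...) {
  tc <- attr(x, "trait_counts")
  if (is.null(tc)) {
    tc <- c(bw2 = sum(!is.na(x$bw2)), bw7 = sum(!is.na(x$bw7)),
            ratio = sum(!is.na(x$ratio)))
  }
  cat("phenotype table:", nrow(x), "birds; records: bw2", tc["bw2"],
      ", bw7", tc["bw7"], ", ratio", tc["ratio"], "\n")
  invisible(x)
}

#' Write phenotypes or a pedigree to delimited text
#'
#' @param x a phenotype table or pedigree.
#' @param path output file path (CSV).
#' @export
write_phenotypes <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("animal", "sire", "dam", "gender",
                                        "batch", "stable", "age_bw2",
                                        "age_bw7", "age_ratio", "person",
                                        "bw2", "bw7", "ratio")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
write_pedigree <- function(x, path) {
  stopifnot(inherits(x, "pedigree"))
  utils::write.csv(data.frame(animal = x$animal, sire = x$sire, dam = x$dam),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop offspring of small sire families
#'
#' Removes all records of sires with fewer than `min_offspring` offspring
#' in the table; large families are needed for unbiased genetic slope
#' variance and slope-intercept correlation estimates. The sires stay in
#' the pedigree, only their offspring's records are dropped. Retained
#' records are unchanged.
#'
#' @param tab a phenotype table.
#' @param min_offspring minimum family size kept (default 20).
#' @return the filtered phenotype table; the number of dropped sires is in
#'   attribute `dropped_sires`.
#' @export
filter_small_sire_families <- function(tab, min_offspring = 20) {
  counts <- table(tab$sire)
  small <- names(counts)[counts < min_offspring]
  out <- tab[!(tab$sire %in% small), , drop = FALSE]
  out <- as_phenotypes(as.data.frame(out))
  attr(out, "dropped_sires") <- small
  out
}

#' Write and read a variance report
#'
#' Serializes a [reml_fit()] to plain text: `<prefix>_components.csv`
#' (component, estimate, SE), `<prefix>_summary.txt` (key = value lines
#' for logL, AIC, BIC, record and parameter counts, convergence), and
#' `<prefix>_solutions.csv` (fixed BLUEs and per-term BLUPs). Estimates are
#' written with 17 significant digits, so a write/read round trip preserves
#' them beyond 12 digits.
#'
#' @param fit a [reml_fit()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return (invisibly) the paths written.
#' @export
write_variance_report <- function(fit, dir, prefix = "fit") {
  stopifnot(inherits(fit, "reml_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) vapply(x, function(v) format(v, digits = 17), character(1))
  p_comp <- file.path(dir, paste0(prefix, "_components.csv"))
  utils::write.csv(data.frame(component = names(fit$components),
                              estimate = fmt(fit$components),
                              se = fmt(fit$se)),
                   p_comp, row.names = FALSE, quote = FALSE)
  p_sum <- file.path(dir, paste0(prefix, "_summary.txt"))
  keys <- c(logL = fit$logL, aic = fit$aic, bic = fit$bic,
            n_records = fit$n_records, n_parameters = fit$n_parameters,
            converged = as.numeric(fit$converged),
            boundary = as.numeric(fit$boundary))
  writeLines(paste0(names(keys), " = ", fmt(keys)), p_sum)
  p_sol <- file.path(dir, paste0(prefix, "_solutions.csv"))
  sol <- data.frame(term = "fixed", id = names(fit$fixed),
                    component = "coef", value = fmt(fit$fixed))
  for (nm in names(fit$ranef)) {
    m <- fit$ranef[[nm]]
    sol <- rbind(sol, data.frame(
      term = nm, id = rep(rownames(m), ncol(m)),
      component = rep(colnames(m), each = nrow(m)),
      value = fmt(as.vector(m))))
  }
  utils::write.csv(sol, p_sol, row.names = FALSE, quote = FALSE)
  invisible(c(p_comp, p_sum, p_sol))
}

#' @rdname write_variance_report
#' @param dir directory the report was written to.
#' @export
read_variance_report <- function(dir, prefix = "fit") {
  comp <- utils::read.csv(file.path(dir, paste0(prefix, "_components.csv")),
                          stringsAsFactors = FALSE)
  comp$estimate <- as.numeric(comp$estimate)
  comp$se <- as.numeric(comp$se)
  lines <- readLines(file.path(dir, paste0(prefix, "_summary.txt")))
  kv <- strsplit(lines, " = ", fixed = TRUE)
  summary <- stats::setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                             vapply(kv, `[`, character(1), 1))
  sol <- utils::read.csv(file.path(dir, paste0(prefix, "_solutions.csv")),
                         stringsAsFactors = FALSE)
  sol$value <- as.numeric(sol$value)
  list(components = comp, summary = summary, solutions = sol)
}

#' Write a trajectory summary
#'
#' Writes the grid trajectory (and the per-class CV table) of a
#' [trajectory_ratios()] result as CSV. An empty trajectory produces a
#' header-only file.
#'
#' @param ts a `trajectory_summary` (or plain data frame).
#' @param path output CSV path; the CV table goes to `<path>` with suffix
#'   `_cv` when `ts` is a full summary.
#' @export
write_trajectory <- function(ts, path) {
  if (inherits(ts, "trajectory_summary")) {
    utils::write.csv(ts$trajectory, path, row.names = FALSE, quote = FALSE)
    cvpath <- sub("(\\.[^.]+)?$", "_cv\\1", path)
    utils::write.csv(ts$cv, cvpath, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(ts, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
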