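#' Read a per-gene score profile from a tab-separated file
#'
#' The profile is the two-column format used throughout the package: gene
#' identifier in the first column and a real-valued differential score (for
#' example the signed confidence score produced by [de_score()]) in a second
#' column. Row order is preserved.
#'
#' @param path Path to a tab-separated text file. A header row is detected
#'   automatically (a non-numeric value in the score column of row 1).
#' @param score_column Name or index of the score column (default: the second
#'   column).
#' @return A named numeric vector of scores, names are gene identifiers.
#' @export
read_profile <- function(path, score_column = 2L) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  first <- utils::read.delim(path, header = FALSE, nrows = 1L,
                             colClasses = "character")
  col <- if (is.character(score_column)) match(score_column, as.character(first)) else score_column
  has_header <- is.character(score_column) ||
    suppressWarnings(is.na(as.numeric(first[[min(2L, ncol(first))]])))
  tab <- utils::read.delim(path, header = has_header, colClasses = "character")
  if (is.character(score_column)) {
    col <- match(score_column, names(tab))
    if (is.na(col)) stop("score column not found: ", score_column)
  }
  genes <- tab[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  scores <- suppressWarnings(as.numeric(tab[[col]]))
  bad <- which(!is.finite(scores))
  if (length(bad)) stop("non-numeric or non-finite score on row ", bad[1L],
                        " (gene ", genes[bad[1L]], ")")
  stats::setNames(scores, genes)
}

#' Write a profile to a tab-separated file
#'
#' @param profile Named numeric vector.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(data.frame(gene = names(profile), score = unname(profile)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Signed confidence score of differential expression
#'
#' Combines a per-gene p-value and fold change into a single signed score,
#' `DE = (1 - p) * sign(log(fold_change))`, which lies in `[-1, 1]`. Genes
#' with fold change exactly 1 (no change) get a score of 0. The fold change
#' may alternatively be supplied as a signed log-fold-change via
#' `log_fc = TRUE`, in which case its sign is used directly.
#'
#' @param p_value Numeric vector of p-values in `[0, 1]`.
#' @param fold_change Positive fold-change ratios (or signed log-fold-changes
#'   when `log_fc = TRUE`).
#' @param genes Optional gene identifiers for naming the result.
#' @param log_fc Interpret `fold_change` as an already-logged value.
#' @return Named (if `genes` given) numeric vector in `[-1, 1]`.
#' @export
de_score <- function(p_value, fold_change, genes = NULL, log_fc = FALSE) {
  if (any(!is.finite(p_value)) || any(p_value < 0 | p_value > 1))
    stop("p_value must lie in [0, 1]")
  s <- if (log_fc) sign(fold_change) else {
    if (any(fold_change <= 0)) stop("fold_change must be positive")
    sign(log(fold_change))
  }
  out <- (1 - p_value) * s
  if (!is.null(genes)) names(out) <- genes
  out
}

#' Read a gene-set annotation in GMT format
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`.
#' Duplicate member genes within a set are collapsed; duplicate set names are
#' an error. Descriptions are preserved in the `"description"` attribute but
#' otherwise unused.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (the member genes of each set).
#' @seealso [write_gmt()], [membership_degree()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate set name(s): ", paste(unique(dup), collapse = ", "))
  desc <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", "")
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("empty gene-set(s): ", paste(nm[empty], collapse = ", "))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' Write a gene-set annotation in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description column (defaults to the
#'   `"description"` attribute if present, else `"na"`).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set membership degree
#'
#' For every gene in the annotation's universe, the number of gene-sets that
#' contain it. This is the bias covariate the enrichment procedure conditions
#' on: promiscuously annotated genes have high degree.
#'
#' @param sets Named list of character vectors.
#' @return Named integer vector over the annotation universe (degree >= 1).
#' @export
membership_degree <- function(sets) {
  tab <- table(unlist(sets, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' Restrict a profile and an annotation to their common gene universe
#'
#' Both objects are restricted to the intersection of the profiled genes and
#' the annotation universe. Sets emptied by the restriction are dropped with a
#' warning. By default the membership degree reported for downstream
#' conditioning is computed on the FULL annotation before restriction: the
#' bias being corrected (study bias, abundance bias) is a property of the
#' annotation, not of the genes one experiment happened to measure. Set
#' `recompute_degree = TRUE` to recompute degrees on the intersection instead.
#'
#' @param profile Named numeric vector.
#' @param sets Named list of character vectors.
#' @param recompute_degree Recompute degrees on the restricted annotation.
#' @return List with elements `profile`, `sets` (both restricted), `degree`
#'   (named integer vector aligned to the restricted profile) and `dropped`
#'   (names of sets removed by the restriction).
#' @export
align_universe <- function(profile, sets, recompute_degree = FALSE) {
  common <- intersect(names(profile), unique(unlist(sets, use.names = FALSE)))
  if (!length(common)) stop("profile and annotation share no genes")
  keep <- names(profile) %in% common
  profile <- profile[keep]
  full_degree <- membership_degree(sets)
  sets2 <- lapply(sets, function(g) g[g %in% common])
  dropped <- names(sets2)[lengths(sets2) == 0L]
  if (length(dropped))
    warning(length(dropped), " set(s) had no measured members and were dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  sets2 <- sets2[lengths(sets2) > 0L]
  degree_src <- if (recompute_degree) membership_degree(sets2) else full_degree
  degree <- degree_src[names(profile)]
  degree[is.na(degree)] <- 0L  # genes measured but absent from restricted sets
  list(profile = profile,
       sets = sets2,
       degree = stats::setNames(as.integer(degree), names(profile)),
       dropped = dropped)
}
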