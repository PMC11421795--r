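#' Read a genes x samples matrix from tab-separated text
#'
#' First column: gene identifiers; header row: sample identifiers.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in matrix")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers in matrix")
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Standardize an expression matrix across samples
#'
#' Per gene: subtract the mean and divide by the (population) standard
#' deviation across samples. Genes with zero variance are set to 0 and listed
#' in the `"flat_genes"` attribute. Re-standardizing a standardized matrix
#' leaves it unchanged.
#'
#' @param m Numeric genes x samples matrix (>= 2 samples).
#' @return Standardized matrix of the same shape.
#' @export
standardize <- function(m) {
  if (ncol(m) < 2L) stop("standardization needs at least 2 samples")
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  flat <- sdev <= 0
  sdev[flat] <- 1
  out <- (m - mu) / sdev
  out[flat, ] <- 0
  attr(out, "flat_genes") <- rownames(m)[flat]
  out
}

#' Per-sample regulon activity
#'
#' For each requested gene-set and each sample, the standardized profile of
#' that sample is discretized into equal-frequency expression bins and the
#' conditional mutual information between set membership and the binned
#' profile (conditioning on membership-degree bins) is computed. The value is
#' normalized by the conditional entropy of membership given the degree bins,
#' `H(Y|Z)`, which analytically bounds the CMI, so the magnitude lies in
#' `[0, 1]` and is comparable across sets and universes. The normalized value
#' is finally signed by the direction of deregulation in that sample
#' (mean-rank rule, see [assign_direction()]). With
#' `normalize = "max"` the values of each set are instead divided by the
#' maximum CMI across samples.
#'
#' @param m Numeric genes x samples matrix (standardized with
#'   [standardize()] unless `standardized = TRUE` already).
#' @param sets Named list of member-gene vectors.
#' @param select Names of the sets to score (default: all).
#' @param n_bins,n_degree_bins Binning parameters (defaults 10 and 3).
#' @param condition Condition on membership degree (default `TRUE`).
#' @param normalize `"entropy"` (default, divide by `H(Y|Z)`) or `"max"`.
#' @param standardized Set to `TRUE` when `m` is already standardized.
#' @param seed Tie-break salt for binning.
#' @return Sets x samples matrix of signed normalized CMI.
#' @export
sample_activity <- function(m, sets, select = names(sets),
                            n_bins = 10L, n_degree_bins = 3L,
                            condition = TRUE,
                            normalize = c("entropy", "max"),
                            standardized = FALSE, seed = 0L) {
  normalize <- match.arg(normalize)
  missing_sets <- setdiff(select, names(sets))
  if (length(missing_sets))
    stop("set(s) absent from annotation: ", paste(missing_sets, collapse = ", "))
  if (!standardized) m <- standardize(m)
  degree <- membership_degree(sets)
  common <- intersect(rownames(m), names(degree))
  if (!length(common)) stop("matrix and annotation share no genes")
  m <- m[common, , drop = FALSE]
  deg <- as.integer(degree[common])
  z <- if (condition) degree_bins(deg, n_degree_bins) else integer(length(common))
  n_z <- max(z) + 1L

  act <- matrix(0, nrow = length(select), ncol = ncol(m),
                dimnames = list(select, colnames(m)))
  for (s in seq_len(ncol(m))) {
    x <- equal_frequency_bins(m[, s], n_bins, genes = common,
                              seed = derive_seed(seed, "bins", s))
    for (i in seq_along(select)) {
      y <- as.integer(common %in% sets[[select[i]]])
      v <- cmi_labels(x, y, z, n_bins, n_z)
      if (normalize == "entropy") {
        h <- cond_entropy_y_given_z(y, z)
        v <- if (h > 0) v / h else 0
      }
      act[i, s] <- v * as.integer(assign_direction(y, m[, s]))
    }
  }
  if (normalize == "max") {
    mx <- apply(abs(act), 1L, max)
    mx[mx <= 0] <- 1
    act <- act / mx
  }
  act
}
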