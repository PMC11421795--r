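#' Equal-frequency discretization of a continuous profile
#'
#' Genes are sorted by score and split into `n_bins` contiguous rank groups
#' whose sizes differ by at most one (the remainder is spread over the
#' lowest-index bins). The probabilities of the information estimator are
#' computed from bin occupancies, so rank-based equal-frequency bins (not
#' equal-width intervals) are used. Ties are broken by a salted hash of the
#' gene identifier so that the labelling is reproducible and independent of
#' the row order of the input.
#'
#' @param values Numeric vector of scores (finite).
#' @param n_bins Number of bins, `1 <= n_bins <= length(values)`.
#' @param genes Optional gene identifiers used for the tie-break; defaults to
#'   `names(values)`, falling back to input position when absent.
#' @param seed Integer salt for the tie-break hash.
#' @return Integer vector of 0-based bin labels aligned to the input order.
#' @export
equal_frequency_bins <- function(values, n_bins, genes = names(values), seed = 0L) {
  n <- length(values)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_bins > n) stop("n_bins (", n_bins, ") exceeds number of values (", n, ")")
  if (any(!is.finite(values))) stop("values must be finite")
  tiekey <- if (is.null(genes)) seq_len(n) else gene_hash(genes, seed)
  ord <- order(values, tiekey)
  labels <- integer(n)
  labels[ord] <- rep.int(seq_len(n_bins) - 1L, bin_sizes(n, n_bins))
  labels
}

#' Equal-frequency binning of membership degrees
#'
#' Degrees are heavily tied (most genes belong to few sets), so ties are kept
#' together whenever possible: when there are fewer distinct degree values
#' than bins, each distinct value gets its own bin (so constant degrees
#' collapse to a single bin and the conditional information estimate reduces
#' to plain mutual information). Otherwise genes are rank-chunked into
#' equal-frequency bins with ties split deterministically by input order.
#'
#' @param degree Integer vector of membership degrees (aligned to the profile).
#' @param n_z Number of degree bins (default 3; `n_z = 1` disables
#'   conditioning).
#' @return Integer vector of 0-based bin labels aligned to the input order.
#' @export
degree_bins <- function(degree, n_z = 3L) {
  if (n_z < 1L) stop("n_z must be >= 1")
  u <- sort(unique(degree))
  if (length(u) < n_z) return(match(degree, u) - 1L)
  n <- length(degree)
  ord <- order(degree, seq_len(n))
  labels <- integer(n)
  labels[ord] <- rep.int(seq_len(n_z) - 1L, bin_sizes(n, n_z))
  labels
}
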