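#' Contingency tensor of expression bins, membership and degree bins
#'
#' Counts genes by the label triple (degree bin z, expression bin x,
#' membership y). No smoothing is applied: the downstream information
#' estimates are plug-in (maximum-likelihood) estimates from these raw
#' occupancies.
#'
#' @param x Integer expression-bin labels (0-based, see
#'   [equal_frequency_bins()]).
#' @param y Membership indicator in `{0, 1}` (or logical).
#' @param z Integer degree-bin labels (0-based); defaults to a single stratum,
#'   which reduces the conditional estimate to plain mutual information.
#' @param n_x,n_z Number of expression / degree bins (inferred from the labels
#'   when omitted).
#' @return Integer array with dim `c(n_z, n_x, 2)`, counts indexed
#'   `[z, x, y]`.
#' @export
contingency_tensor <- function(x, y, z = NULL, n_x = NULL, n_z = NULL) {
  n <- length(x)
  y <- as.integer(y)
  if (length(y) != n) stop("x and y differ in length")
  if (any(y != 0L & y != 1L)) stop("y must be a binary membership indicator")
  if (is.null(z)) z <- integer(n)
  if (length(z) != n) stop("x and z differ in length")
  n_x <- n_x %||% (max(x) + 1L)
  n_z <- n_z %||% (max(z) + 1L)
  idx <- z + n_z * (x + n_x * y)  # [z, x, y] in column-major order
  counts <- tabulate(idx + 1L, nbins = n_z * n_x * 2L)
  array(as.integer(counts), dim = c(n_z, n_x, 2L))
}

#' Conditional mutual information from a contingency tensor
#'
#' Plug-in estimate of I(X;Y|Z) in bits:
#' `sum_z p(z) sum_{x,y} p(x,y|z) log2( p(x,y|z) / (p(x|z) p(y|z)) )`.
#' Cells with zero joint probability contribute 0; empty degree strata
#' contribute 0 through `p(z) = 0`; values in `(-1e-12, 0)` arising from
#' floating-point rounding are clamped to 0.
#'
#' @param counts Array of non-negative counts with dim `c(n_z, n_x, 2)`
#'   (see [contingency_tensor()]).
#' @return Non-negative scalar, in bits.
#' @export
cmi <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("all-zero contingency tensor")
  m_zx <- apply(counts, c(1L, 2L), sum)
  m_zy <- apply(counts, c(1L, 3L), sum)
  m_z <- rowSums(m_zx)
  d <- dim(counts)
  zi <- slice.index(counts, 1L)
  xi <- slice.index(counts, 2L)
  yi <- slice.index(counts, 3L)
  pos <- counts > 0
  c_ <- counts[pos]
  ratio <- c_ * m_z[zi[pos]] / (m_zx[cbind(zi[pos], xi[pos])] * m_zy[cbind(zi[pos], yi[pos])])
  v <- sum(c_ / n * log2(ratio))
  max(v, 0)
}

#' Mutual information between two label vectors
#'
#' Plug-in estimate in bits; identical to [cmi()] with a single (constant)
#' conditioning stratum. Accepts arbitrary integer labellings of either
#' vector.
#'
#' @param a,b Aligned label vectors (coerced via `as.integer(factor(.))`).
#' @return Non-negative scalar, in bits.
#' @export
mutual_info <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  pr <- rowSums(tab); pc <- colSums(tab)
  pos <- tab > 0
  ri <- slice.index(tab, 1L); ci <- slice.index(tab, 2L)
  v <- sum(tab[pos] / n * log2(tab[pos] * n / (pr[ri[pos]] * pc[ci[pos]])))
  max(v, 0)
}

#' Conditional mutual information of a candidate set given an accepted set
#'
#' I(candidate; expression | accepted): the conditioning variable is the
#' binary membership in an already-accepted set (two strata). This is the
#' numerator of the information-ratio redundancy criterion.
#'
#' @param candidate Binary membership vector of the candidate set.
#' @param x Integer expression-bin labels.
#' @param conditioning_set Binary membership vector of the accepted set.
#' @param n_x Number of expression bins (inferred when omitted).
#' @return Non-negative scalar, in bits.
#' @export
cmi_given_set <- function(candidate, x, conditioning_set, n_x = NULL) {
  n_x <- n_x %||% (max(x) + 1L)
  cmi_labels_cpp(as.integer(x), as.integer(candidate),
                 as.integer(conditioning_set), n_x, 2L)
}

# Fast path used in hot loops: CMI directly from aligned label vectors.
cmi_labels <- function(x, y, z, n_x, n_z) {
  cmi_labels_cpp(as.integer(x), as.integer(y), as.integer(z),
                 as.integer(n_x), as.integer(n_z))
}

# Conditional entropy H(Y|Z) in bits of a binary membership given degree
# bins; the normalizer for per-sample activity (I(X;Y|Z) <= H(Y|Z)).
cond_entropy_y_given_z <- function(y, z) {
  tab <- table(z, y)
  n <- sum(tab)
  hz <- 0
  for (i in seq_len(nrow(tab))) {
    nz <- sum(tab[i, ])
    if (nz == 0) next
    p <- tab[i, ][tab[i, ] > 0] / nz
    hz <- hz + nz / n * (-sum(p * log2(p)))
  }
  hz
}
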