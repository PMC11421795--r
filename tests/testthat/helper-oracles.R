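# Independent oracles used to check the package's fast implementations.
# These deliberately use naive loops / closed forms, never the code paths
# they validate.

# Plug-in conditional mutual information by literal triple summation.
naive_cmi <- function(counts) {
  n <- sum(counts)
  v <- 0
  for (z in seq_len(dim(counts)[1])) {
    nz <- sum(counts[z, , ])
    if (nz == 0) next
    pz <- nz / n
    for (x in seq_len(dim(counts)[2])) {
      for (y in 1:2) {
        c_ <- counts[z, x, y]
        if (c_ == 0) next
        p_xy_z <- c_ / nz
        p_x_z <- sum(counts[z, x, ]) / nz
        p_y_z <- sum(counts[z, , y]) / nz
        v <- v + pz * p_xy_z * log2(p_xy_z / (p_x_z * p_y_z))
      }
    }
  }
  v
}

# Contingency counting by a literal per-gene loop.
naive_counts <- function(x, y, z, n_x, n_z) {
  counts <- array(0L, dim = c(n_z, n_x, 2L))
  for (i in seq_along(x)) {
    counts[z[i] + 1L, x[i] + 1L, y[i] + 1L] <-
      counts[z[i] + 1L, x[i] + 1L, y[i] + 1L] + 1L
  }
  counts
}

# PR AUC by exhaustive threshold enumeration: at every distinct score used
# as a cutoff (score >= t called positive), accumulate precision * recall
# increment.
enum_pr_auc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  auc <- 0
  P <- sum(labels)
  for (t in ths) {
    called <- scores >= t
    tp <- sum(called & labels)
    precision <- tp / sum(called)
    recall <- tp / P
    auc <- auc + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  auc
}

# ROC AUC via the rank (Mann-Whitney) closed form with midrank ties.
enum_roc_auc <- function(scores, labels) {
  r <- rank(scores)
  P <- sum(labels); N <- sum(!labels)
  (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
}

# Exact hypergeometric upper/lower tail by direct summation over the
# point masses (choose()-based), for small instances.
enum_hyper_tails <- function(k, K, n, bin) {
  pm <- function(i) choose(K, i) * choose(n - K, bin - i) / choose(n, bin)
  support <- max(0, bin - (n - K)):min(K, bin)
  list(over = sum(vapply(support[support >= k], pm, 0)),
       under = sum(vapply(support[support <= k], pm, 0)))
}
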