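#' Rank gene-sets by conditional mutual information
#'
#' Computes the CMI between the binned profile and each set's membership
#' indicator, conditioned on degree bins, and returns the sets in descending
#' CMI order (ties broken by set name for determinism).
#'
#' @param profile Named numeric vector (aligned to the annotation, see
#'   [align_universe()]).
#' @param sets Named list of member-gene vectors.
#' @param degree Named integer membership degrees aligned to `profile`.
#' @param n_bins,n_degree_bins Numbers of expression / degree bins.
#' @param condition If `FALSE`, a single degree stratum is used and the
#'   statistic reduces to plain mutual information (the unconditioned
#'   baseline).
#' @param seed Tie-break salt for the binning.
#' @return Data frame with columns `set`, `size` (measured members) and
#'   `cmi`, in descending CMI order.
#' @export
rank_by_cmi <- function(profile, sets, degree, n_bins = 10L, n_degree_bins = 3L,
                        condition = TRUE, seed = 0L) {
  if (!length(sets)) stop("empty annotation")
  x <- equal_frequency_bins(profile, n_bins, seed = seed)
  z <- if (condition) degree_bins(degree, n_degree_bins) else integer(length(profile))
  n_z <- max(z) + 1L
  genes <- names(profile)
  vals <- vapply(sets, function(members) {
    y <- as.integer(genes %in% members)
    cmi_labels(x, y, z, n_bins, n_z)
  }, numeric(1))
  ord <- order(-vals, names(sets))
  data.frame(set = names(sets)[ord],
             size = vapply(sets, length, 0L)[ord],
             cmi = unname(vals)[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation p-value of a gene-set's conditional mutual information
#'
#' The expression bin labels are randomly shuffled across genes (membership
#' and degree labels stay fixed) and the CMI is recomputed each time.
#' Significance is the proportion of permutations whose CMI strictly exceeds
#' the observed value. By default the add-one estimator
#' `(1 + b) / (1 + n_perm)` is reported, which avoids p = 0 and keeps
#' Benjamini-Hochberg well defined; `raw = TRUE` restores the raw proportion
#' `b / n_perm`.
#'
#' @param members Binary membership vector aligned to the labels.
#' @param x Integer expression-bin labels.
#' @param z Integer degree-bin labels (`NULL` for unconditioned).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed (set just before shuffling).
#' @param raw Report the raw proportion instead of the add-one estimator.
#' @return Scalar p-value.
#' @export
permutation_pvalue <- function(members, x, z = NULL, n_perm = 1000L,
                               seed = NULL, raw = FALSE) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.null(z)) z <- integer(length(x))
  if (!is.null(seed)) set.seed(seed)
  b <- perm_exceed_cpp(as.integer(x), as.integer(members), as.integer(z),
                       max(x) + 1L, max(z) + 1L, as.integer(n_perm))
  if (raw) b / n_perm else (1 + b) / (1 + n_perm)
}

#' Sequential permutation testing with early stopping
#'
#' Sets are tested in descending-CMI order. A set is significant when its
#' permutation p-value is below `alpha`. When `stop_after` consecutive
#' insignificant results occur, testing stops and all remaining sets are left
#' untested (p-value `NA`).
#'
#' @param ranked Character vector of set names in descending-CMI order.
#' @param p_fun Function taking a set name and returning its p-value.
#' @param alpha Significance level.
#' @param stop_after Number of consecutive insignificant results that stops
#'   the scan (use `Inf` to test everything).
#' @return Data frame with columns `set`, `p_value` (`NA` when untested),
#'   `tested` and `significant`.
#' @export
sequential_test <- function(ranked, p_fun, alpha = 0.01, stop_after = 5L) {
  if (stop_after < 1) stop("stop_after must be >= 1")
  n <- length(ranked)
  p <- rep(NA_real_, n)
  run <- 0L
  for (i in seq_len(n)) {
    p[i] <- p_fun(ranked[i])
    if (p[i] < alpha) run <- 0L else run <- run + 1L
    if (run >= stop_after) break
  }
  tested <- !is.na(p)
  data.frame(set = ranked, p_value = p, tested = tested,
             significant = tested & !is.na(p) & p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Information-ratio redundancy filter
#'
#' Walks the significant sets in descending-CMI order. The first set is
#' always accepted; each later candidate must add information beyond every
#' already-accepted set:
#' `I(candidate; expression | accepted) / I(candidate; accepted) > r`
#' for all accepted sets. A pair with `I(candidate; accepted) = 0` (disjoint
#' sets) imposes no constraint: a set sharing no information with the
#' accepted ones cannot be redundant with them. An exact duplicate of an
#' accepted set has numerator 0 and positive denominator, so it is rejected
#' for any `r > 0`.
#'
#' @param significant Character vector of significant set names in
#'   descending-CMI order.
#' @param membership Function mapping a set name to its binary membership
#'   vector, or a named list of such vectors.
#' @param x Integer expression-bin labels.
#' @param r Redundancy ratio threshold (>= 0; default 0.1, useful values lie
#'   between 0 and 0.5).
#' @return Character vector of accepted set names, with per-pair ratios in
#'   the `"ratios"` attribute for auditing.
#' @export
redundancy_filter <- function(significant, membership, x, r = 0.1) {
  if (r < 0) stop("r must be >= 0")
  if (!is.function(membership)) {
    memb_list <- membership
    membership <- function(nm) memb_list[[nm]]
  }
  accepted <- character(0)
  acc_y <- list()
  audit <- list()
  n_x <- max(x) + 1L
  for (nm in significant) {
    y_c <- as.integer(membership(nm))
    ok <- TRUE
    ratios <- numeric(0)
    for (j in seq_along(acc_y)) {
      den <- mutual_info(y_c, acc_y[[j]])
      if (den <= 1e-12) { ratios[accepted[j]] <- Inf; next }
      num <- cmi_given_set(y_c, x, acc_y[[j]], n_x = n_x)
      ratios[accepted[j]] <- num / den
      if (num / den <= r) { ok <- FALSE; break }
    }
    audit[[nm]] <- ratios
    if (ok) {
      accepted <- c(accepted, nm)
      acc_y[[length(acc_y) + 1L]] <- y_c
    }
  }
  attr(accepted, "ratios") <- audit
  accepted
}

#' Signed per-bin hypergeometric enrichment scores
#'
#' For each expression bin, two hypergeometric tail p-values are computed:
#' over-representation (probability of observing at least the member count
#' seen in the bin) and under-representation (at most that count). The
#' smaller of the two is log10-transformed; over-represented bins are flipped
#' to positive sign. These scores colour the enrichment heatmap.
#'
#' @param members Binary membership vector aligned to the labels.
#' @param x Integer expression-bin labels.
#' @param n_x Number of bins (inferred when omitted).
#' @return Numeric vector of signed scores, one per bin (positive =
#'   over-represented).
#' @export
bin_scores <- function(members, x, n_x = NULL) {
  n_x <- n_x %||% (max(x) + 1L)
  members <- as.integer(members)
  n <- length(x)
  K <- sum(members)
  nb <- tabulate(x + 1L, nbins = n_x)
  k <- tabulate(x[members == 1L] + 1L, nbins = n_x)
  p_over <- stats::phyper(k - 1L, K, n - K, nb, lower.tail = FALSE)
  p_under <- stats::phyper(k, K, n - K, nb)
  score <- log10(pmin(p_over, p_under))
  ifelse(p_over < p_under, -score, score)
}

#' Direction of deregulation of a gene-set
#'
#' `+1` when the mean score-rank of the member genes exceeds the mean rank of
#' the universe (members sit high in the profile), `-1` otherwise. An exact
#' tie resolves to `+1` by convention and is flagged in the `"near_tie"`
#' attribute.
#'
#' @param members Binary membership vector.
#' @param scores Numeric profile scores aligned to `members`.
#' @return `+1` or `-1`, with a logical `"near_tie"` attribute.
#' @export
assign_direction <- function(members, scores) {
  rk <- rank(scores)
  delta <- mean(rk[as.logical(members)]) - (length(scores) + 1) / 2
  out <- if (delta >= 0) 1L else -1L
  attr(out, "near_tie") <- abs(delta) < 1e-9
  out
}

#' Conditional-mutual-information gene-set enrichment
#'
#' The end-to-end procedure: align the profile and annotation to their common
#' universe, discretize the profile into equal-frequency expression bins and
#' the membership degrees into degree bins, rank all sets by conditional
#' mutual information, test them sequentially by permutation with early
#' stopping, optionally apply Benjamini-Hochberg correction, filter redundant
#' sets by the information ratio, and score each significant set per bin with
#' signed hypergeometric statistics.
#'
#' @param profile Named numeric vector of per-gene scores (e.g. from
#'   [de_score()] or [read_profile()]).
#' @param sets Named list of member-gene vectors (e.g. from [read_gmt()]).
#' @param n_bins Number of expression bins (default 10).
#' @param n_degree_bins Number of membership-degree bins (default 3).
#' @param alpha Significance level for the permutation test (default 0.01).
#' @param n_perm Number of permutations per set (default 1000).
#' @param stop_after Consecutive insignificant sets that stop testing
#'   (default 5; `Inf` tests everything).
#' @param redundancy Information-ratio threshold `r` (default 0.1).
#' @param bh Apply Benjamini-Hochberg correction across tested sets;
#'   significance is then judged on the adjusted p-values (default `FALSE`).
#' @param condition Condition on membership degree (default `TRUE`;
#'   `FALSE` reproduces the unconditioned legacy behaviour).
#' @param recompute_degree Compute degrees on the measured universe instead
#'   of the full annotation (default `FALSE`; see [align_universe()]).
#' @param raw_p Use the raw permutation proportion instead of the add-one
#'   estimator.
#' @param adaptive_perm Escalate to `10 * n_perm` permutations when a
#'   p-value lands within a factor of two of `alpha` (default `FALSE`).
#' @param seed Integer seed; every stochastic step derives its own stream
#'   from it, so results are fully reproducible.
#' @return An object of class `"cmipage"`: a list with `results` (one row per
#'   set: `set`, `size`, `cmi`, `p_value`, `tested`, `significant`,
#'   `accepted`, `direction`, `near_tie`), `heatmap` (signed bin-score matrix
#'   for significant sets), `config`, `n_genes` and `dropped`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 2000, n_sets = 40,
#'                                    n_perturbed = 8, max_size = 200),
#'                         seed = 1)
#' fit <- cmipage(sim$profile, sim$sets, n_perm = 200, seed = 1)
#' head(as.data.frame(fit))
#' @export
cmipage <- function(profile, sets,
                    n_bins = 10L, n_degree_bins = 3L,
                    alpha = 0.01, n_perm = 1000L, stop_after = 5L,
                    redundancy = 0.1, bh = FALSE, condition = TRUE,
                    recompute_degree = FALSE, raw_p = FALSE,
                    adaptive_perm = FALSE, seed = 0L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  aligned <- align_universe(profile, sets, recompute_degree = recompute_degree)
  prof <- aligned$profile
  sets_a <- aligned$sets
  genes <- names(prof)
  x <- equal_frequency_bins(prof, n_bins, seed = derive_seed(seed, "bins"))
  z <- if (condition) degree_bins(aligned$degree, n_degree_bins)
       else integer(length(prof))
  n_z <- max(z) + 1L

  membership <- function(nm) as.integer(genes %in% sets_a[[nm]])

  cmis <- vapply(names(sets_a), function(nm)
    cmi_labels(x, membership(nm), z, n_bins, n_z), numeric(1))
  ord <- order(-cmis, names(sets_a))
  ranked <- names(sets_a)[ord]

  p_fun <- function(nm) {
    p <- permutation_pvalue(membership(nm), x, z, n_perm = n_perm,
                            seed = derive_seed(seed, "perm", nm), raw = raw_p)
    if (adaptive_perm && p >= alpha / 2 && p <= alpha * 2) {
      p <- permutation_pvalue(membership(nm), x, z, n_perm = 10L * n_perm,
                              seed = derive_seed(seed, "perm2", nm),
                              raw = raw_p)
    }
    p
  }
  tested <- sequential_test(ranked, p_fun, alpha = alpha,
                            stop_after = stop_after)
  if (bh) {
    tested$p_adjusted <- NA_real_
    tested$p_adjusted[tested$tested] <- stats::p.adjust(
      tested$p_value[tested$tested], method = "BH")
    tested$significant <- tested$tested & !is.na(tested$p_adjusted) &
      tested$p_adjusted < alpha
  }

  sig <- tested$set[tested$significant]
  accepted <- redundancy_filter(sig, membership, x, r = redundancy)

  direction <- integer(length(sig)); near <- logical(length(sig))
  hm <- matrix(NA_real_, nrow = length(sig), ncol = n_bins,
               dimnames = list(sig, paste0("bin", seq_len(n_bins) - 1L)))
  for (i in seq_along(sig)) {
    y <- membership(sig[i])
    hm[i, ] <- bin_scores(y, x, n_x = n_bins)
    d <- assign_direction(y, prof)
    direction[i] <- d; near[i] <- attr(d, "near_tie")
  }

  res <- tested
  res$cmi <- unname(cmis[res$set])
  res$size <- vapply(sets_a[res$set], length, 0L)
  res$accepted <- res$set %in% accepted
  res$direction <- NA_integer_; res$near_tie <- NA
  res$direction[match(sig, res$set)] <- direction
  res$near_tie[match(sig, res$set)] <- near
  cols <- c("set", "size", "cmi", "p_value",
            if (bh) "p_adjusted", "tested", "significant", "accepted",
            "direction", "near_tie")
  res <- res[, cols]

  structure(list(
    results = res,
    heatmap = hm,
    accepted = accepted,
    config = list(n_bins = n_bins, n_degree_bins = n_degree_bins,
                  alpha = alpha, n_perm = n_perm, stop_after = stop_after,
                  redundancy = redundancy, bh = bh, condition = condition,
                  recompute_degree = recompute_degree, raw_p = raw_p,
                  adaptive_perm = adaptive_perm, seed = seed),
    n_genes = length(prof),
    dropped = aligned$dropped
  ), class = "cmipage")
}

#' @export
print.cmipage <- function(x, ...) {
  cat("Conditional mutual information gene-set enrichment\n")
  cat(sprintf("  %d genes, %d sets (%d tested, %d significant, %d accepted)\n",
              x$n_genes, nrow(x$results), sum(x$results$tested),
              sum(x$results$significant), length(x$accepted)))
  cat(sprintf("  bins: %d expression x %d degree; alpha %.3g; %d permutations%s\n",
              x$config$n_bins, x$config$n_degree_bins, x$config$alpha,
              x$config$n_perm,
              if (x$config$condition) "" else " (unconditioned)"))
  if (length(x$accepted)) {
    cat("  accepted sets:\n")
    top <- x$results[x$results$accepted, c("set", "cmi", "p_value", "direction")]
    print(utils::head(top, 10L), row.names = FALSE)
    if (nrow(top) > 10L) cat("  ...", nrow(top) - 10L, "more\n")
  }
  invisible(x)
}

#' @export
summary.cmipage <- function(object, ...) {
  r <- object$results
  out <- list(
    n_genes = object$n_genes, n_sets = nrow(r),
    n_tested = sum(r$tested), n_significant = sum(r$significant),
    n_accepted = length(object$accepted),
    accepted = r[r$accepted, c("set", "size", "cmi", "p_value", "direction")]
  )
  class(out) <- "summary.cmipage"
  out
}

#' @export
print.summary.cmipage <- function(x, ...) {
  cat(sprintf("cmipage fit: %d genes, %d sets; tested %d, significant %d, accepted %d\n",
              x$n_genes, x$n_sets, x$n_tested, x$n_significant, x$n_accepted))
  if (nrow(x$accepted)) print(x$accepted, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cmipage <- function(x, ...) x$results

#' Heatmap of per-bin enrichment scores
#'
#' Rows are significant gene-sets (accepted sets marked `*`), columns are
#' expression bins ordered from most down- to most up-regulated; colour is
#' the signed log10 hypergeometric score (red = over-represented).
#'
#' @param x A `"cmipage"` object.
#' @param accepted_only Plot only sets that passed the redundancy filter.
#' @param ... Passed to [graphics::image()].
#' @export
plot.cmipage <- function(x, accepted_only = TRUE, ...) {
  hm <- x$heatmap
  if (accepted_only) hm <- hm[rownames(hm) %in% x$accepted, , drop = FALSE]
  if (!nrow(hm)) { warning("nothing to plot: no significant sets"); return(invisible(NULL)) }
  lim <- max(abs(hm), 1e-9)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  op <- graphics::par(mar = c(4, 10, 2, 1)); on.exit(graphics::par(op))
  graphics::image(x = seq_len(ncol(hm)), y = seq_len(nrow(hm)),
                  z = t(hm[rev(seq_len(nrow(hm))), , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "expression bin (low → high)", ylab = "", ...)
  lab <- rev(rownames(hm))
  lab[lab %in% x$accepted] <- paste0(lab[lab %in% x$accepted], " *")
  graphics::axis(2, at = seq_len(nrow(hm)), labels = lab, las = 2, cex.axis = 0.7)
  graphics::axis(1, at = seq_len(ncol(hm)),
                 labels = seq_len(ncol(hm)) - 1L, cex.axis = 0.7)
  invisible(x)
}
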