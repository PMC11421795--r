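#' Score an enrichment run against simulation truth
#'
#' Turns a fitted enrichment object and the generator's ground truth into
#' per-set (score, label) pairs for curve computation. The ranking score is
#' `1 - p` (the benchmark judges significance calls); sets left untested by
#' the early stop score 0 and therefore count as misses. `rank_by = "cmi"`
#' switches to ranking by the raw information value instead.
#'
#' @param fit A `"cmipage"` object.
#' @param truth Data frame with columns `set` and `label` (see
#'   [simulate_dataset()]).
#' @param rank_by `"p"` (default) or `"cmi"`.
#' @return Data frame with columns `set`, `score` and `label` (logical,
#'   `TRUE` for truly perturbed sets).
#' @export
score_run <- function(fit, truth, rank_by = c("p", "cmi")) {
  rank_by <- match.arg(rank_by)
  res <- fit$results
  if (!setequal(res$set, truth$set))
    stop("enrichment result and truth cover different sets")
  lab <- truth$label[match(res$set, truth$set)] != "none"
  score <- if (rank_by == "cmi") res$cmi else {
    s <- 1 - res$p_value
    s[!res$tested] <- 0
    s
  }
  data.frame(set = res$set, score = score, label = lab,
             stringsAsFactors = FALSE, row.names = NULL)
}

check_two_classes <- function(labels) {
  if (!any(labels) || all(labels))
    stop("curve computation needs both classes present")
}

# Cumulative TP/FP at each distinct score threshold, descending.
threshold_counts <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  idx <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie block
  list(tp = cumsum(l)[idx], fp = cumsum(!l)[idx],
       thresholds = s[idx], P = sum(l), N = sum(!l))
}

#' Precision-recall curve and area
#'
#' The curve steps through the distinct score thresholds in descending
#' order; no linear interpolation between precision points is performed.
#' The area is the integral of the stepped precision over recall
#' (equivalently the sum of precision times recall increment at every
#' threshold).
#'
#' @param scores Numeric ranking scores (higher = more likely perturbed).
#' @param labels Logical truth labels.
#' @return List with `recall`, `precision`, `thresholds` and `auc`.
#' @export
pr_curve <- function(scores, labels) {
  check_two_classes(labels)
  tc <- threshold_counts(scores, labels)
  recall <- tc$tp / tc$P
  precision <- tc$tp / (tc$tp + tc$fp)
  auc <- sum(diff(c(0, recall)) * precision)
  list(recall = recall, precision = precision,
       thresholds = tc$thresholds, auc = auc)
}

#' Receiver-operating-characteristic curve and area
#'
#' Standard ROC with trapezoidal area (ties handled as a single threshold
#' block, so the AUC equals the Mann-Whitney statistic).
#'
#' @inheritParams pr_curve
#' @return List with `fpr`, `tpr`, `thresholds` and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  check_two_classes(labels)
  tc <- threshold_counts(scores, labels)
  fpr <- c(0, tc$fp / tc$N)
  tpr <- c(0, tc$tp / tc$P)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr[-1], tpr = tpr[-1], thresholds = tc$thresholds, auc = auc)
}

#' Detection-error-tradeoff curve and area
#'
#' False-negative rate against false-positive rate across thresholds, with
#' trapezoidal area (lower is better).
#'
#' @inheritParams pr_curve
#' @return List with `fpr`, `fnr`, `thresholds` and `auc`.
#' @export
det_curve <- function(scores, labels) {
  check_two_classes(labels)
  tc <- threshold_counts(scores, labels)
  fpr <- c(0, tc$fp / tc$N)
  fnr <- c(1, 1 - tc$tp / tc$P)
  auc <- sum(diff(fpr) * (utils::head(fnr, -1) + utils::tail(fnr, -1)) / 2)
  list(fpr = fpr[-1], fnr = fnr[-1], thresholds = tc$thresholds, auc = auc)
}

#' Realized false-discovery proportion across nominal levels
#'
#' For each nominal level, sets with `p < alpha` are called significant and
#' the realized false-discovery proportion among the calls is reported
#' (0 when nothing is called).
#'
#' @param p_values Per-set p-values (`NA` = untested, never called).
#' @param labels Logical truth labels.
#' @param alphas Grid of nominal levels.
#' @return List with `alpha`, `fdp` and `n_called`.
#' @export
fdr_curve <- function(p_values, labels, alphas = seq(0.001, 0.2, by = 0.001)) {
  check_two_classes(labels)
  fdp <- vapply(alphas, function(a) {
    called <- !is.na(p_values) & p_values < a
    if (!any(called)) 0 else sum(called & !labels) / sum(called)
  }, numeric(1))
  n_called <- vapply(alphas, function(a) sum(!is.na(p_values) & p_values < a), 0)
  list(alpha = alphas, fdp = fdp, n_called = n_called)
}

#' Intersection-over-union of two accepted-set lists
#'
#' Consistency measure between two runs over the same annotation (for
#' example with and without gene subsampling). Two empty outputs are defined
#' as perfectly consistent (1.0).
#'
#' @param run_a,run_b `"cmipage"` objects or character vectors of accepted
#'   set names.
#' @return Scalar in `[0, 1]`.
#' @export
consistency_iou <- function(run_a, run_b) {
  a <- if (inherits(run_a, "cmipage")) run_a$accepted else as.character(run_a)
  b <- if (inherits(run_b, "cmipage")) run_b$accepted else as.character(run_b)
  u <- length(union(a, b))
  if (u == 0L) return(1.0)
  length(intersect(a, b)) / u
}

#' Benchmark the enrichment method on simulated data
#'
#' Runs the full simulate-fit-score loop over a grid of scenarios
#' (monotonic/dual regulation, with/without bias injection) and methods
#' (degree-conditioned vs unconditioned), with a fresh seeded dataset per
#' iteration. Reports PR/ROC AUCs and the fraction of perturbed sets
#' recovered as significant at `alpha` per iteration, plus per-scenario
#' means and standard deviations.
#'
#' @param cfg Base [sim_config()] (its `scenario` and `bias` fields are
#'   overridden by the grid).
#' @param scenarios Data frame with columns `regulation`
#'   (`"monotonic"`/`"dual"`) and `bias` (logical); defaults to all four
#'   combinations.
#' @param methods Character subset of `c("conditioned", "unconditioned")`.
#' @param n_iterations Iterations per scenario (default 20).
#' @param alpha,n_perm,stop_after Enrichment parameters passed to
#'   [cmipage()].
#' @param seed Integer seed.
#' @return Object of class `"benchmark_report"`: list with `metrics` (one
#'   row per scenario x method x iteration) and `summary` (means and SDs).
#' @export
run_benchmark <- function(cfg = sim_config(),
                          scenarios = expand.grid(
                            regulation = c("monotonic", "dual"),
                            bias = c(FALSE, TRUE),
                            stringsAsFactors = FALSE),
                          methods = c("conditioned", "unconditioned"),
                          n_iterations = 20L,
                          alpha = 0.01, n_perm = 1000L, stop_after = 5L,
                          seed = 0L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (cfg$n_perturbed == 0L)
    stop("degenerate benchmark: no perturbed sets in the simulation config")
  rows <- list()
  for (sc in seq_len(nrow(scenarios))) {
    reg <- scenarios$regulation[sc]; bias <- scenarios$bias[sc]
    cfg_sc <- cfg
    cfg_sc$scenario <- reg; cfg_sc$bias <- bias
    for (it in seq_len(n_iterations)) {
      sim <- simulate_dataset(cfg_sc,
                              seed = derive_seed(seed, "bench", reg, bias, it))
      for (m in methods) {
        fit <- cmipage(sim$profile, sim$sets,
                       alpha = alpha, n_perm = n_perm, stop_after = stop_after,
                       condition = (m == "conditioned"),
                       seed = derive_seed(seed, "fit", reg, bias, it, m))
        sr <- score_run(fit, sim$truth)
        perturbed <- sim$truth$set[sim$truth$label != "none"]
        rec <- mean(fit$results$significant[match(perturbed, fit$results$set)])
        rows[[length(rows) + 1L]] <- data.frame(
          regulation = reg, bias = bias, method = m, iteration = it,
          pr_auc = pr_curve(sr$score, sr$label)$auc,
          roc_auc = roc_curve(sr$score, sr$label)$auc,
          recovery = rec, stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  summ <- stats::aggregate(cbind(pr_auc, roc_auc, recovery) ~
                             regulation + bias + method,
                           data = metrics, FUN = mean)
  sds <- stats::aggregate(cbind(pr_auc, roc_auc, recovery) ~
                            regulation + bias + method,
                          data = metrics, FUN = stats::sd)
  names(sds)[4:6] <- paste0(names(sds)[4:6], "_sd")
  summ <- merge(summ, sds, by = c("regulation", "bias", "method"))
  structure(list(metrics = metrics, summary = summ,
                 n_iterations = n_iterations),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Simulation benchmark (", x$n_iterations, "iteration(s) per scenario )\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Robustness of planted-set recovery to input degradation
#'
#' Two degradation modes: `"signal"` sweeps the `signal_fraction` knob of
#' the generator (weakening the planted signal); `"subsample"` removes a
#' uniform random fraction of genes from the profile before analysis
#' (annotation degrees are retained from the full annotation). At every
#' grid point the fraction of ground-truth perturbed sets called
#' significant at `alpha` is reported, averaged over `n_iterations` seeded
#' datasets. With `use_accepted = TRUE` recovery counts only sets that also
#' pass the redundancy filter.
#'
#' @param cfg Base [sim_config()].
#' @param mode `"signal"` or `"subsample"`.
#' @param grid Numeric grid in `(0, 1]` (signal fractions or kept-gene
#'   fractions).
#' @param n_iterations Seeded datasets per grid point.
#' @param alpha,n_perm,stop_after Enrichment parameters.
#' @param use_accepted Count post-redundancy acceptance instead of
#'   significance.
#' @param seed Integer seed.
#' @return Data frame with columns `value` (grid point), `iteration` and
#'   `recovery`.
#' @export
robustness_sweep <- function(cfg = sim_config(),
                             mode = c("signal", "subsample"),
                             grid = seq(0.1, 1, by = 0.1),
                             n_iterations = 5L,
                             alpha = 0.01, n_perm = 1000L, stop_after = 5L,
                             use_accepted = FALSE, seed = 0L) {
  mode <- match.arg(mode)
  if (!length(grid)) stop("empty grid")
  if (any(grid <= 0 | grid > 1)) stop("grid values must lie in (0, 1]")
  rows <- list()
  for (g in grid) {
    for (it in seq_len(n_iterations)) {
      cfg_g <- cfg
      if (mode == "signal") cfg_g$signal_fraction <- g
      sim <- simulate_dataset(cfg_g, seed = derive_seed(seed, "sweep", it))
      prof <- sim$profile
      if (mode == "subsample")
        prof <- subsample_profile(prof, g, seed = derive_seed(seed, "sub", g, it))
      fit <- cmipage(prof, sim$sets, alpha = alpha, n_perm = n_perm,
                     stop_after = stop_after,
                     seed = derive_seed(seed, "fit", mode, g, it))
      perturbed <- sim$truth$set[sim$truth$label != "none"]
      res <- fit$results
      hit <- if (use_accepted) res$accepted else res$significant
      kept <- match(perturbed, res$set)       # sets can drop out entirely
      rec <- sum(hit[kept[!is.na(kept)]]) / length(perturbed)
      rows[[length(rows) + 1L]] <- data.frame(value = g, iteration = it,
                                              recovery = rec)
    }
  }
  do.call(rbind, rows)
}
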