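#' Simulation configuration
#'
#' Bundles the parameters of the synthetic benchmark generator. The defaults
#' are the benchmark's study conditions: 15000 genes; 1100 gene-sets of which
#' 100 are perturbed; heavy-tailed set sizes from a discrete power law on
#' `[min_size, max_size]`; planted signals matched to truncated normal
#' distributions on `[-1, 1]` whose mean is drawn uniformly from
#' `(0.5, 1)` (up) or `(-1, -0.5)` (down) and whose standard deviation is
#' drawn uniformly from `(0.1, 0.2)`; a 33% noise admixture per perturbed
#' set; and, when enabled, a promiscuous-gene bias pool of 2000 genes of
#' which 100 are appended to every set.
#'
#' `snr` and `signal_fraction` are two parameterizations of the same signal
#' share: the effective fraction of a perturbed set drawn from the signal
#' model is `(1 - snr) * signal_fraction / 0.5` (capped at 1), so the two
#' defaults coincide at a 67% share and sweeping `signal_fraction` rescales
#' the share multiplicatively.
#'
#' @param n_genes,n_sets,n_perturbed Problem size.
#' @param min_size,max_size,tail_exponent Discrete power-law set-size law
#'   (the empirical transcription-factor regulon size distribution this
#'   emulates is not published; these are exposed, documented placeholders).
#' @param mu_up,mu_down,sigma_range Truncated-normal parameter ranges.
#' @param snr Fraction of each perturbed set drawn at random (noise).
#' @param signal_fraction Multiplicative signal-share knob (default 0.5).
#' @param scenario `"monotonic"` (perturbed sets split 50/50 up/down) or
#'   `"dual"` (every perturbed set mixes both signal models).
#' @param bias Append promiscuous pool genes to every set.
#' @param pool_size,n_added Bias-pool size and genes appended per set.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 15000L, n_sets = 1100L, n_perturbed = 100L,
                       min_size = 50L, max_size = 1500L, tail_exponent = 1.5,
                       mu_up = c(0.5, 1), mu_down = c(-1, -0.5),
                       sigma_range = c(0.1, 0.2),
                       snr = 0.33, signal_fraction = 0.5,
                       scenario = c("monotonic", "dual"),
                       bias = FALSE, pool_size = 2000L, n_added = 100L) {
  scenario <- match.arg(scenario)
  if (n_perturbed > n_sets) stop("n_perturbed exceeds n_sets")
  if (snr < 0 || snr > 1) stop("snr must lie in [0, 1]")
  if (signal_fraction < 0 || signal_fraction > 1)
    stop("signal_fraction must lie in [0, 1]")
  if (min_size < 1L) stop("min_size must be >= 1")
  if (min_size > max_size) stop("min_size exceeds max_size")
  if (bias && n_added > pool_size) stop("n_added exceeds pool_size")
  structure(list(n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
                 n_perturbed = as.integer(n_perturbed),
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 tail_exponent = tail_exponent,
                 mu_up = mu_up, mu_down = mu_down, sigma_range = sigma_range,
                 snr = snr, signal_fraction = signal_fraction,
                 scenario = scenario, bias = bias,
                 pool_size = as.integer(pool_size),
                 n_added = as.integer(n_added)),
            class = "sim_config")
}

#' Simulate a null differential-expression profile
#'
#' Without a template, scores are drawn i.i.d. uniform on `[-1, 1]` (the
#' range of the signed confidence score of [de_score()]). With a template
#' profile, its scores are randomly permuted across synthetic gene
#' identifiers, which destroys the informational content while preserving
#' the empirical score distribution.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param template Optional numeric vector of real scores to permute (must
#'   have at least `n_genes` entries).
#' @return Named numeric vector (`g00001`, `g00002`, ...).
#' @export
simulate_null_profile <- function(n_genes, seed = 0L, template = NULL) {
  set.seed(derive_seed(seed, "null_profile"))
  scores <- if (is.null(template)) {
    stats::runif(n_genes, -1, 1)
  } else {
    if (length(template) < n_genes) stop("template has fewer than n_genes entries")
    sample(as.numeric(template), n_genes)
  }
  stats::setNames(scores, sprintf("g%05d", seq_len(n_genes)))
}

#' Sample heavy-tailed gene-set sizes
#'
#' Sizes follow a discrete power law `P(s) proportional to s^-tail_exponent`
#' on `[min_size, max_size]`, giving many small sets and a long right tail
#' (median below mean).
#'
#' @param n_sets Number of sizes to draw.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return Integer vector of length `n_sets`.
#' @export
sample_set_sizes <- function(n_sets, cfg = sim_config(), seed = 0L) {
  set.seed(derive_seed(seed, "set_sizes"))
  support <- cfg$min_size:cfg$max_size
  if (length(support) == 1L) return(rep.int(support, n_sets))
  w <- support^(-cfg$tail_exponent)
  sample(support, n_sets, replace = TRUE, prob = w / sum(w))
}

# Truncated-normal draws on [lo, hi] by inverse-CDF.
rtrunc_norm <- function(n, mu, sigma, lo = -1, hi = 1) {
  plo <- stats::pnorm((lo - mu) / sigma)
  phi <- stats::pnorm((hi - mu) / sigma)
  mu + sigma * stats::qnorm(plo + stats::runif(n) * (phi - plo))
}

# Greedy nearest-value matching without replacement: for each target value in
# draw order, pick the unused gene whose score is closest.  Operates on the
# score-sorted order; returns positions in the sorted order.
match_targets <- function(sorted_scores, targets, used) {
  n <- length(sorted_scores)
  picked <- integer(length(targets))
  for (k in seq_along(targets)) {
    t <- targets[k]
    left <- findInterval(t, sorted_scores)
    right <- left + 1L
    while (left >= 1L && used[left]) left <- left - 1L
    while (right <= n && used[right]) right <- right + 1L
    pick <- if (left < 1L) right
            else if (right > n) left
            else if (t - sorted_scores[left] <= sorted_scores[right] - t) left
            else right
    if (pick < 1L || pick > n) stop("insufficient unused genes for signal matching")
    used[pick] <- TRUE
    picked[k] <- pick
  }
  picked
}

#' Plant a perturbed gene-set in a profile
#'
#' The signal members are chosen by sampling target values from a truncated
#' normal on `[-1, 1]` (mean drawn from `mu_up` for an up-set, `mu_down` for
#' a down-set; a dual set splits its draws half-and-half between both
#' models) and greedily matching each draw, in draw order, to the unused
#' gene whose score is closest. The remaining members (the noise admixture)
#' are drawn uniformly from genes not yet in the set.
#'
#' @param profile Named numeric profile.
#' @param size Set size.
#' @param label `"up"`, `"down"` or `"dual"`.
#' @param cfg A [sim_config()] (supplies the signal-share and distribution
#'   parameters).
#' @param seed Integer seed.
#' @return Character vector of member gene identifiers.
#' @export
plant_set <- function(profile, size, label = c("up", "down", "dual"),
                      cfg = sim_config(), seed = 0L) {
  label <- match.arg(label)
  if (size > length(profile)) stop("set size exceeds number of genes")
  set.seed(derive_seed(seed, "plant", label, size))
  share <- min(1, (1 - cfg$snr) * cfg$signal_fraction / 0.5)
  n_signal <- round(size * share)
  ord <- order(profile)
  ss <- unname(profile[ord])
  used <- logical(length(profile))

  draw_side <- function(n, mu_range) {
    mu <- stats::runif(1, mu_range[1], mu_range[2])
    sigma <- stats::runif(1, cfg$sigma_range[1], cfg$sigma_range[2])
    rtrunc_norm(n, mu, sigma)
  }
  targets <- switch(label,
    up = draw_side(n_signal, cfg$mu_up),
    down = draw_side(n_signal, cfg$mu_down),
    dual = {
      n_up <- n_signal %/% 2L
      c(draw_side(n_up, cfg$mu_up), draw_side(n_signal - n_up, cfg$mu_down))
    })
  pos <- if (n_signal > 0L) match_targets(ss, targets, used) else integer(0)
  members <- names(profile)[ord][pos]
  n_noise <- size - n_signal
  if (n_noise > 0L) {
    rest <- setdiff(names(profile), members)
    if (length(rest) < n_noise) stop("insufficient unused genes for noise admixture")
    members <- c(members, sample(rest, n_noise))
  }
  members
}

#' Inject promiscuous-gene bias into an annotation
#'
#' A fixed pool of `pool_size` genes is chosen once (seed-deterministic);
#' every set is concatenated with `n_added` genes sampled from the pool
#' (without duplicating genes already in the set). Pool genes thereby occur
#' far more often than other genes, pushing the right tail of the
#' membership-degree distribution above its unbiased shape.
#'
#' @param sets Named list of member-gene vectors.
#' @param genes Gene population to draw the pool from.
#' @param cfg A [sim_config()] (supplies `pool_size` and `n_added`).
#' @param seed Integer seed.
#' @return List with `sets` (biased annotation) and `pool` (the pool genes).
#' @export
inject_bias <- function(sets, genes, cfg = sim_config(bias = TRUE), seed = 0L) {
  if (cfg$pool_size > length(genes)) stop("pool_size exceeds number of genes")
  if (cfg$n_added > cfg$pool_size) stop("n_added exceeds pool_size")
  set.seed(derive_seed(seed, "bias_pool"))
  pool <- sample(genes, cfg$pool_size)
  biased <- sets
  for (i in seq_along(biased)) {
    set.seed(derive_seed(seed, "bias_set", names(sets)[i]))
    candidates <- setdiff(pool, biased[[i]])
    take <- min(cfg$n_added, length(candidates))
    biased[[i]] <- c(biased[[i]], sample(candidates, take))
  }
  list(sets = biased, pool = pool)
}

#' Simulate a complete benchmark dataset
#'
#' Composes the generator: a null profile, heavy-tailed set sizes, planted
#' perturbed sets (up/down in the monotonic scenario, mixed in the dual
#' scenario), uniformly random unperturbed sets, and optional bias
#' injection. The ground-truth perturbation label of every set is returned
#' alongside the data.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param template Optional template profile passed to
#'   [simulate_null_profile()].
#' @return List with `profile` (named numeric), `sets` (named list),
#'   `truth` (data frame `set`, `label` with labels in
#'   none/up/down/dual), and `pool` (bias pool genes, `NULL` when bias is
#'   off).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 0L, template = NULL) {
  profile <- simulate_null_profile(cfg$n_genes, seed = seed, template = template)
  sizes <- sample_set_sizes(cfg$n_sets, cfg, seed = seed)
  labels <- rep("none", cfg$n_sets)
  if (cfg$n_perturbed > 0L) {
    idx <- seq_len(cfg$n_perturbed)  # perturbed sets first; names carry no truth
    labels[idx] <- if (cfg$scenario == "dual") "dual"
                   else rep_len(c("up", "down"), cfg$n_perturbed)
  }
  sets <- vector("list", cfg$n_sets)
  names(sets) <- sprintf("set%04d", seq_len(cfg$n_sets))
  for (i in seq_len(cfg$n_sets)) {
    if (labels[i] == "none") {
      set.seed(derive_seed(seed, "random_set", i))
      sets[[i]] <- sample(names(profile), sizes[i])
    } else {
      sets[[i]] <- plant_set(profile, sizes[i], labels[i], cfg,
                             seed = derive_seed(seed, "planted", i))
    }
  }
  pool <- NULL
  if (cfg$bias) {
    b <- inject_bias(sets, names(profile), cfg, seed = seed)
    sets <- b$sets
    pool <- b$pool
  }
  list(profile = profile, sets = sets,
       truth = data.frame(set = names(sets), label = labels,
                          stringsAsFactors = FALSE),
       pool = pool)
}

#' Subsample a profile to a fraction of its genes
#'
#' Uniform random gene removal, emulating sparser measurements (for example
#' single-cell capture). The annotation is left untouched downstream:
#' [align_universe()] keeps full-annotation degrees by default.
#'
#' @param profile Named numeric vector.
#' @param fraction Fraction of genes to keep, in `(0, 1]`.
#' @param seed Integer seed.
#' @return The subsampled profile (original order preserved).
#' @export
subsample_profile <- function(profile, fraction, seed = 0L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (fraction == 1) return(profile)
  set.seed(derive_seed(seed, "subsample"))
  keep <- sort(sample(length(profile), round(length(profile) * fraction)))
  profile[keep]
}
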