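make_profile <- function(n, seed = 1) {
  set.seed(seed)
  setNames(runif(n, -1, 1), sprintf("g%04d", seq_len(n)))
}

test_that("ranking places a top-decile set above a random set of equal size", {
  prof <- make_profile(1000)
  top <- names(sort(prof, decreasing = TRUE))[1:50]
  set.seed(2)
  rand <- sample(names(prof), 50)
  sets <- list(planted = top, random = rand, dup = top)
  deg <- setNames(rep(1L, length(prof)), names(prof))
  rk <- rank_by_cmi(prof, sets, deg)
  expect_identical(rk$set[1:2], c("dup", "planted"))  # equal CMI, name order
  expect_equal(rk$cmi[1], rk$cmi[2])
  expect_lt(rk$cmi[rk$set == "random"], rk$cmi[rk$set == "planted"] / 5)
  expect_error(rank_by_cmi(prof, list(), deg), "empty annotation")
})

test_that("a maximal-CMI set attains the minimum permutation p-value", {
  prof <- make_profile(200)
  x <- equal_frequency_bins(prof, 10)
  members <- as.integer(x == 9L)       # exactly the top bin
  p <- permutation_pvalue(members, x, n_perm = 99, seed = 4)
  expect_equal(p, 1 / 100)
  # raw proportion flag restores b / N
  p_raw <- permutation_pvalue(members, x, n_perm = 99, seed = 4, raw = TRUE)
  expect_equal(p_raw, 0)
  # seed determinism
  y2 <- as.integer(runif(200) < 0.2)
  expect_identical(permutation_pvalue(y2, x, n_perm = 200, seed = 7),
                   permutation_pvalue(y2, x, n_perm = 200, seed = 7))
})

test_that("sequential testing stops after a run of insignificant results", {
  pseq <- c(.001, .2, .3, .4, .5, .6, .002, .001)
  nm <- paste0("s", seq_along(pseq))
  p_fun <- function(s) pseq[match(s, nm)]
  out <- sequential_test(nm, p_fun, alpha = 0.01, stop_after = 5)
  expect_equal(sum(out$tested), 6)          # stops after the 6th entry
  expect_true(is.na(out$p_value[7]))        # the .002 set is never tested
  expect_identical(out$significant, c(TRUE, rep(FALSE, 7)))

  all_sig <- sequential_test(nm, function(s) 0.001, alpha = 0.01, stop_after = 5)
  expect_true(all(all_sig$tested))

  one <- sequential_test(nm, p_fun, alpha = 0.01, stop_after = 1)
  expect_equal(sum(one$tested), 2)          # first insignificant result stops
})

test_that("early stop yields a subset of the exhaustive significant list", {
  prof <- make_profile(800, seed = 3)
  set.seed(8)
  sets <- c(list(top = names(sort(prof, decreasing = TRUE))[1:40]),
            lapply(setNames(1:30, paste0("null", 1:30)),
                   function(i) sample(names(prof), 40)))
  fit_stop <- cmipage(prof, sets, n_perm = 200, stop_after = 5, seed = 5)
  fit_all <- cmipage(prof, sets, n_perm = 200, stop_after = Inf, seed = 5)
  sig_stop <- fit_stop$results$set[fit_stop$results$significant]
  sig_all <- fit_all$results$set[fit_all$results$significant]
  expect_true(all(sig_stop %in% sig_all))
})

test_that("the redundancy filter rejects duplicates and passes disjoint sets", {
  prof <- make_profile(600, seed = 6)
  x <- equal_frequency_bins(prof, 10)
  genes <- names(prof)
  top <- genes[x >= 8L]
  bottom <- genes[x <= 1L]
  memb <- function(gs) as.integer(genes %in% gs)
  sets <- list(A = memb(top), A_dup = memb(top), B = memb(bottom))

  acc <- redundancy_filter(c("A", "A_dup", "B"), sets, x, r = 0.05)
  expect_identical(as.character(acc), c("A", "B"))  # duplicate rejected, disjoint kept
  ratios <- attr(acc, "ratios")
  expect_lt(ratios$A_dup["A"], 1e-10)
  expect_gt(ratios$B["A"], 0.05)  # opposite-tail set adds information

  # a candidate exactly independent of the accepted set has a zero
  # denominator and passes unconstrained
  y_a <- rep(c(1L, 0L), each = 300)
  y_c <- as.integer(seq_len(600) %% 4L == 0L)   # proportional in both strata
  expect_lt(mutual_info(y_c, y_a), 1e-12)
  acc_ind <- redundancy_filter(c("A", "C"), list(A = y_a, C = y_c), x, r = 0.5)
  expect_identical(as.character(acc_ind), c("A", "C"))
  expect_identical(unname(attr(acc_ind, "ratios")$C["A"]), Inf)

  # with r = 0 even the duplicate's ratio 0 fails the strict > r test
  acc0 <- redundancy_filter(c("A", "A_dup"), sets, x, r = 0)
  expect_identical(as.character(acc0), "A")
  expect_error(redundancy_filter("A", sets, x, r = -1), ">= 0")
})

test_that("nested-set redundancy decisions match direct ratio evaluation", {
  prof <- make_profile(600, seed = 9)
  x <- equal_frequency_bins(prof, 10)
  genes <- names(prof)
  big <- genes[x >= 7L]                   # accepted superset
  half <- genes[x == 9L]                  # informative half, nested
  memb <- function(gs) as.integer(genes %in% gs)
  num <- cmi_given_set(memb(half), x, memb(big))
  den <- mutual_info(memb(half), memb(big))
  for (r in c(0.05, 0.5, 5)) {
    acc <- redundancy_filter(c("big", "half"),
                             list(big = memb(big), half = memb(half)), x, r = r)
    expect_identical("half" %in% acc, num / den > r)
  }
})

test_that("bin scores match exact hypergeometric tails and sign conventions", {
  n <- 100
  x <- rep(0:9, each = 10)
  members <- as.integer(x == 3L)          # all 10 members in bin 3
  sc <- bin_scores(members, x)
  or <- enum_hyper_tails(10, 10, 100, 10)
  expect_equal(sc[4], -log10(or$over), tolerance = 1e-10)
  expect_gt(sc[4], 0)                     # over-represented bin is positive
  # bins with zero members but high expected count are negative
  expect_true(all(sc[-4] < 0))

  # proportional membership: no bin is strongly scored
  members2 <- as.integer(seq_len(n) %% 10 == 0)  # one member per bin
  expect_true(all(abs(bin_scores(members2, x)) < 1))
})

test_that("direction follows the mean member rank with tie flagged positive", {
  prof <- make_profile(100, seed = 10)
  ord <- order(prof)
  top <- logical(100); top[ord[91:100]] <- TRUE
  bottom <- logical(100); bottom[ord[1:10]] <- TRUE
  expect_equal(as.integer(assign_direction(top, prof)), 1L)
  expect_equal(as.integer(assign_direction(bottom, prof)), -1L)
  sym <- logical(100); sym[ord[c(1:5, 96:100)]] <- TRUE   # perfectly symmetric
  d <- assign_direction(sym, prof)
  expect_equal(as.integer(d), 1L)
  expect_true(attr(d, "near_tie"))
})

test_that("the full fit recovers planted sets and is seed-reproducible", {
  cfg <- sim_config(n_genes = 3000, n_sets = 100, n_perturbed = 10,
                    max_size = 300)
  sim <- simulate_dataset(cfg, seed = 12)
  fit <- cmipage(sim$profile, sim$sets, n_perm = 300, seed = 12)
  perturbed <- sim$truth$set[sim$truth$label != "none"]
  hits <- fit$results$significant[match(perturbed, fit$results$set)]
  expect_gte(sum(hits), 9)

  fit2 <- cmipage(sim$profile, sim$sets, n_perm = 300, seed = 12)
  expect_identical(fit$results, fit2$results)
  expect_identical(fit$heatmap, fit2$heatmap)

  # directions: up-sets positive, down-sets negative
  up <- sim$truth$set[sim$truth$label == "up"]
  down <- sim$truth$set[sim$truth$label == "down"]
  res <- fit$results
  expect_true(all(res$direction[match(up, res$set)] == 1L, na.rm = TRUE))
  expect_true(all(res$direction[match(down, res$set)] == -1L, na.rm = TRUE))
})

test_that("disabling conditioning reproduces an unconditioned reference run", {
  cfg <- sim_config(n_genes = 2000, n_sets = 40, n_perturbed = 6,
                    max_size = 200)
  sim <- simulate_dataset(cfg, seed = 14)
  fit_off <- cmipage(sim$profile, sim$sets, n_perm = 200, condition = FALSE,
                     seed = 14)
  # reference: same pipeline with a constant degree covariate
  flat <- sim$sets
  prof <- sim$profile
  deg <- setNames(rep(1L, length(prof)), names(prof))
  rk_ref <- rank_by_cmi(align_universe(prof, flat)$profile,
                        align_universe(prof, flat)$sets,
                        deg[names(align_universe(prof, flat)$profile)],
                        condition = FALSE)
  rk_off <- fit_off$results[order(-fit_off$results$cmi, fit_off$results$set), ]
  expect_equal(rk_off$cmi, rk_ref$cmi, tolerance = 1e-12)
  expect_identical(rk_off$set, rk_ref$set)
})

test_that("print, summary, as.data.frame and plot methods work", {
  cfg <- sim_config(n_genes = 1500, n_sets = 30, n_perturbed = 5,
                    max_size = 150)
  sim <- simulate_dataset(cfg, seed = 15)
  fit <- cmipage(sim$profile, sim$sets, n_perm = 100, seed = 15)
  expect_output(print(fit), "accepted")
  expect_output(print(summary(fit)), "cmipage fit")
  expect_s3_class(as.data.frame(fit), "data.frame")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); on.exit(grDevices::dev.off(), add = TRUE)
  expect_silent(plot(fit))
})

test_that("Benjamini-Hochberg option adjusts only tested sets", {
  prof <- make_profile(500, seed = 16)
  set.seed(16)
  sets <- c(list(top = names(sort(prof, decreasing = TRUE))[1:30]),
            lapply(setNames(1:20, paste0("n", 1:20)),
                   function(i) sample(names(prof), 30)))
  fit <- cmipage(prof, sets, n_perm = 200, bh = TRUE, seed = 16)
  res <- fit$results
  expect_true(all(is.na(res$p_adjusted[!res$tested])))
  tested <- res[res$tested, ]
  expect_equal(tested$p_adjusted,
               p.adjust(tested$p_value, method = "BH"))
  expect_true(all(tested$p_adjusted >= tested$p_value))
})
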