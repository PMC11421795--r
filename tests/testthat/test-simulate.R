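test_that("null profiles conserve a template's values and respect bounds", {
  tpl <- c(0.1, -0.4, 0.9, 0.2, -0.8, 0.5, 0.3, -0.1, 0.7, -0.6)
  p <- simulate_null_profile(10, seed = 1, template = tpl)
  expect_setequal(unname(p), tpl)
  expect_error(simulate_null_profile(20, template = tpl), "fewer")

  p2 <- simulate_null_profile(10000, seed = 2)
  expect_true(all(p2 >= -1 & p2 <= 1))
  expect_lt(abs(mean(p2)), 0.03)

  expect_identical(simulate_null_profile(100, seed = 3),
                   simulate_null_profile(100, seed = 3))
})

test_that("set sizes follow a bounded heavy-tailed law", {
  cfg <- sim_config(min_size = 100, max_size = 100)
  expect_true(all(sample_set_sizes(50, cfg, seed = 1) == 100))

  sizes <- sample_set_sizes(1100, sim_config(), seed = 4)
  expect_true(all(sizes >= 50 & sizes <= 1500))
  expect_lt(median(sizes), mean(sizes))   # heavier mass at small sizes

  expect_identical(sample_set_sizes(200, sim_config(), seed = 5),
                   sample_set_sizes(200, sim_config(), seed = 5))
})

test_that("planted up-sets sit at the top of the profile when noise-free", {
  prof <- simulate_null_profile(5000, seed = 6)
  cfg <- sim_config(snr = 0, mu_up = c(0.97, 1), sigma_range = c(0.05, 0.1))
  members <- plant_set(prof, 50, "up", cfg, seed = 7)
  expect_length(members, 50)
  expect_false(anyDuplicated(members) > 0)
  expect_gt(mean(prof[members]), 0.8)
})

test_that("full-noise planted sets are indistinguishable from random draws", {
  prof <- simulate_null_profile(3000, seed = 8)
  cfg <- sim_config(snr = 1)
  members <- plant_set(prof, 200, "up", cfg, seed = 9)
  expect_length(members, 200)
  expect_lt(abs(mean(prof[members])), 0.12)   # ~ mean of 200 uniform draws
})

test_that("dual sets are bimodal with balanced tails", {
  prof <- simulate_null_profile(5000, seed = 10)
  members <- plant_set(prof, 400, "dual", sim_config(), seed = 11)
  frac_pos <- mean(prof[members] > 0)
  expect_gt(frac_pos, 0.4)
  expect_lt(frac_pos, 0.6)
  # signal genes concentrate at both extremes
  expect_gt(mean(abs(prof[members]) > 0.4), 0.5)
})

test_that("bias injection concentrates degree on the promiscuous pool", {
  cfg <- sim_config(n_genes = 15000, n_sets = 300, n_perturbed = 0,
                    max_size = 200, bias = TRUE)
  sim0 <- simulate_dataset(sim_config(n_genes = 15000, n_sets = 300,
                                      n_perturbed = 0, max_size = 200),
                           seed = 12)
  b <- inject_bias(sim0$sets, names(sim0$profile), cfg, seed = 12)
  deg <- membership_degree(b$sets)
  pool_deg <- mean(deg[names(deg) %in% b$pool])
  other_deg <- mean(deg[!names(deg) %in% b$pool])
  # expectation oracle: pool genes gain n_sets * n_added / pool_size entries
  # on top of the background membership every gene shares
  base <- cfg$n_sets * mean(lengths(sim0$sets)) / cfg$n_genes
  extra <- cfg$n_sets * cfg$n_added / cfg$pool_size
  expect_equal(pool_deg, base + extra, tolerance = 0.15)
  expect_gt(pool_deg / other_deg, 5)
  # sets never contain duplicated genes after injection
  expect_true(all(vapply(b$sets, function(s) !anyDuplicated(s), TRUE)))
  # every set gained exactly n_added members
  expect_equal(lengths(b$sets), lengths(sim0$sets) + cfg$n_added,
               ignore_attr = TRUE)
})

test_that("dataset composition matches the configured truth structure", {
  cfg <- sim_config(n_genes = 4000, n_sets = 60, n_perturbed = 12,
                    max_size = 300)
  sim <- simulate_dataset(cfg, seed = 13)
  expect_length(sim$sets, 60)
  expect_equal(sum(sim$truth$label != "none"), 12)
  expect_setequal(unique(sim$truth$label), c("none", "up", "down"))

  dual <- simulate_dataset(sim_config(n_genes = 4000, n_sets = 60,
                                      n_perturbed = 12, max_size = 300,
                                      scenario = "dual"), seed = 13)
  expect_setequal(unique(dual$truth$label), c("none", "dual"))

  null_only <- simulate_dataset(sim_config(n_genes = 2000, n_sets = 20,
                                           n_perturbed = 0, max_size = 200),
                                seed = 14)
  expect_true(all(null_only$truth$label == "none"))
})

test_that("a seed reproduces byte-identical profile and annotation files", {
  cfg <- sim_config(n_genes = 2000, n_sets = 30, n_perturbed = 6,
                    max_size = 200, bias = TRUE,
                    pool_size = 400, n_added = 20)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- simulate_dataset(cfg, seed = 15)
    write_profile(sim$profile, file.path(d, "profile.tsv"))
    write_gmt(sim$sets, file.path(d, "annotation.gmt"))
  }
  expect_identical(readBin(file.path(d1, "profile.tsv"), "raw", 1e6),
                   readBin(file.path(d2, "profile.tsv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "annotation.gmt"), "raw", 1e6),
                   readBin(file.path(d2, "annotation.gmt"), "raw", 1e6))
})

test_that("planted signals are detectable while unperturbed sets are null", {
  cfg <- sim_config(n_genes = 5000, n_sets = 40, n_perturbed = 10,
                    max_size = 300)
  sim <- simulate_dataset(cfg, seed = 16)
  x <- equal_frequency_bins(sim$profile, 10)
  deg <- membership_degree(sim$sets)[names(sim$profile)]
  deg[is.na(deg)] <- 0L
  z <- degree_bins(as.integer(deg), 3)
  pvals <- vapply(seq_len(40), function(i) {
    y <- as.integer(names(sim$profile) %in% sim$sets[[i]])
    permutation_pvalue(y, x, z, n_perm = 200, seed = 100 + i)
  }, numeric(1))
  planted <- sim$truth$label != "none"
  expect_lt(median(pvals[planted]), 0.01)
  expect_gt(median(pvals[!planted]), 0.2)
})
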