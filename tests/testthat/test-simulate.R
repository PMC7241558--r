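test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config()
  p1 <- simulate_panel(cfg, seed = 5)
  p2 <- simulate_panel(cfg, seed = 5)
  expect_identical(p1$matrix$A, p2$matrix$A)
  expect_identical(p1$sites$info, p2$sites$info)
  expect_identical(p1$taxonomy, p2$taxonomy)
  p3 <- simulate_panel(cfg, seed = 6)
  expect_false(identical(p1$sites$info$pos, p3$sites$info$pos))

  t1 <- simulate_trajectories(cfg, "cold", seed = 3, n_replicates = 2)
  t2 <- simulate_trajectories(cfg, "cold", seed = 3, n_replicates = 2)
  expect_identical(t1, t2)

  o1 <- simulate_pool(rep(1 / 13, 13), p1$matrix, 30, seed = 4)
  o2 <- simulate_pool(rep(1 / 13, 13), p1$matrix, 30, seed = 4)
  expect_identical(o1$b, o2$b)
  expect_identical(o1$w, o2$w)

  # the global RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_panel(cfg, seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated panels satisfy the downstream contracts", {
  p <- study_panel()
  expect_true(differentiates_taxa(p$matrix))
  expect_equal(dim(p$matrix), c(197L, 13L))
  expect_equal(table(p$site_class)[["private"]], 10L)
  mult <- site_multiplicity(p$matrix)
  expect_true(all(mult >= 1 & mult <= 12))
  # genotypes are clones of their strain's genotype
  expect_equal(nrow(p$genotypes), 47L)
  expect_equal(length(unique(apply(p$genotypes, 1, paste, collapse = ""))), 13L)
  # emitted frequencies pass the marker filter without repair
  filt <- filter_marker_candidates(p$sites)
  expect_equal(n_sites(filt), 197L)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulate_panel(sim_config(clade_sizes = c(I = 1L),
                                         superclades = list(I = "I")),
                              seed = 1),
               "single strain")
  # two strains, one private site each: identity-like panel
  cfg2 <- sim_config(n_lines = 4L, clade_sizes = c(A = 1L, B = 1L),
                     superclades = list(A = "A", B = "B"),
                     n_superclade_sites = 0L, n_clade_sites = 0L,
                     n_strain_shared_sites = 0L, n_decoy_sites = 0L,
                     n_mt_superclade_sites = 2L, n_mt_within_sites = 0L,
                     clade_cut = 0.5, superclade_cut = 1.5)
  p2 <- simulate_panel(cfg2, seed = 1)
  expect_equal(sort(as.vector(p2$matrix$A)), c(0, 0, 1, 1))
  expect_true(differentiates_taxa(p2$matrix))
})

test_that("neutral trajectories conserve frequencies in expectation", {
  cfg <- sim_config(pop_size = 200L, generations = c(0L, 20L))
  tr <- simulate_trajectories(cfg, "base", seed = 17, n_replicates = 200)
  x0 <- tr[[1]]["0", ]
  finals <- t(vapply(tr, function(m) m["20", ], numeric(13)))
  se <- apply(finals, 2, sd) / sqrt(nrow(finals))
  # 4 SE per strain keeps the family-wise false-positive rate for 13
  # simultaneous comparisons below 1e-3
  expect_true(all(abs(colMeans(finals) - x0) <= 4 * se + 1e-12))
})

test_that("strong selection drives the favoured strain to fixation", {
  cfg <- sim_config(clade_sizes = c(I = 2L, III = 2L),
                    superclades = list("I+III" = c("I", "III")),
                    n_lines = 8L,
                    selection = list(hot = list(strains = "s01",
                                                fitness = 2, onset = 0L)))
  tr <- simulate_trajectories(cfg, "hot", seed = 21, n_replicates = 3,
                              generations = c(0L, 100L), pop_size = 1000L)
  for (m in tr) expect_gt(m["100", "s01"], 0.99)

  # absent strains stay absent (no mutation)
  tr0 <- simulate_trajectories(cfg, "hot", seed = 22, n_replicates = 2,
                               x0 = c(0, 0.5, 0.5, 0))
  for (m in tr0) expect_true(all(m[, c("s01", "s04")] == 0))
})

test_that("pooled observations converge to the expected frequencies", {
  p <- simulate_panel(mini_config(), seed = 2)
  x <- c(0.1, 0.2, 0.3, 0.4)
  obs <- simulate_pool(x, p$matrix, coverage_mean = 1e5, seed = 13)
  expect_lt(max(abs(obs$b - as.vector(p$matrix$A %*% x))), 0.01)

  # a pure pool concentrates on one design column
  e1 <- c(1, 0, 0, 0)
  obs1 <- simulate_pool(e1, p$matrix, coverage_mean = 1e4, seed = 14)
  expect_lt(max(abs(obs1$b - p$matrix$A[, 1])), 0.05)

  expect_error(simulate_pool(c(0.5, 0.6, 0, 0), p$matrix, 30, seed = 1),
               "simplex")
})

test_that("GC coverage generator honours its null cases", {
  sim <- simulate_gc_coverage(length_target = 2e4, length_norm = 2e4,
                              copy_ratio = 1,
                              bias_function = function(gc) rep(1, length(gc)),
                              seed = 19)
  expect_lt(abs(mean(sim$target$depth) / mean(sim$norm$depth) - 1), 0.05)

  sim0 <- simulate_gc_coverage(length_target = 1000, length_norm = 1000,
                               depth_mean = 0, seed = 20)
  expect_true(all(sim0$target$depth == 0))
})

test_that("co-transmitted panels share the signal; the smaller panel is noisier", {
  cfg <- sim_config()
  p <- simulate_panel(cfg, seed = 42)
  tr <- simulate_trajectories(cfg, "cold", seed = 7, n_replicates = 3)
  ct <- simulate_cotransmission(tr, p, coverage_mean = 30, seed = 8,
                                regime = "cold")
  expect_equal(dim(ct$wol_matrix), c(155L, 3L))
  expect_equal(dim(ct$mt_matrix), c(21L, 3L))

  sw <- fit_pool_series(ct$wolbachia_pools, ct$wol_matrix)
  sm <- fit_pool_series(ct$mtdna_pools, ct$mt_matrix)
  truth <- ct$samples
  key <- function(d) paste(d$replicate, d$generation, d$taxon)
  ew <- abs(sw$frequency - truth$frequency[match(key(sw), key(truth))])
  em <- abs(sm$frequency - truth$frequency[match(key(sm), key(truth))])
  expect_gt(mean(em), mean(ew))
})
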