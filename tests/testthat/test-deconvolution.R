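test_that("exact fits are recovered on identifiable designs", {
  mm <- marker_matrix(rbind(c(1, 0), c(0, 1)), check = TRUE)
  f <- fit_strain_frequencies(mm, pool_observation(c(0.3, 0.7), c(10, 10)))
  expect_equal(unname(coef(f)), c(0.3, 0.7), tolerance = 1e-10)
  expect_equal(f$objective, 0, tolerance = 1e-10)

  A <- rbind(diag(3), 1 - diag(3))
  x_star <- c(0.2, 0.3, 0.5)
  mm3 <- marker_matrix(A, check = TRUE)
  f3 <- fit_strain_frequencies(mm3,
          pool_observation(as.vector(A %*% x_star), rep(7, 6)))
  expect_equal(unname(coef(f3)), x_star, tolerance = 1e-10)
  expect_equal(sum(coef(f3)), 1, tolerance = 1e-8)
})

test_that("private markers with equal weights recover per-strain medians", {
  # 2 strains x 3 private sites each; medians 0.3 and 0.7 sum to 1
  A <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 1))
  mm <- marker_matrix(A, check = TRUE)
  b <- c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8)
  f <- fit_strain_frequencies(mm, pool_observation(b, rep(5, 6)))
  expect_equal(unname(coef(f)), c(0.3, 0.7), tolerance = 1e-10)

  # the same holds for 3 strains with odd private-site counts
  A3 <- matrix(0, 9, 3)
  A3[1:3, 1] <- A3[4:6, 2] <- A3[7:9, 3] <- 1
  med <- c(0.2, 0.3, 0.5)
  b3 <- as.vector(sapply(med, function(m) m + c(-0.05, 0, 0.05)))
  f3 <- fit_strain_frequencies(marker_matrix(A3, check = TRUE),
                               pool_observation(b3, rep(1, 9)))
  expect_equal(unname(coef(f3)), med, tolerance = 1e-10)
})

test_that("LP optimum matches the exhaustive grid search on noisy instances", {
  set.seed(206)
  for (rep in 1:5) {
    A <- rand_panel(4, 10)
    x0 <- as.vector(rmultinom(1, 25, rep(1, 4))) / 25
    w <- rpois(nrow(A), 30) + 1
    b <- rbinom(nrow(A), w, pmin(1, pmax(0, as.vector(A %*% x0)))) / w
    fit <- fit_strain_frequencies(marker_matrix(A, check = TRUE),
                                  pool_observation(b, w))
    oracle <- grid_search_wl1(A, b, w, step = 0.01)
    # the LP can only be at least as good as the grid
    expect_lte(fit$objective, oracle$objective + 1e-9)
    if (fit$solver_status == "optimal" && oracle$localized) {
      expect_lt(max(abs(coef(fit) - oracle$x)), 0.01 + 1e-9)
    }
  }
})

test_that("LP and smoothed solvers agree on non-degenerate instances", {
  set.seed(207)
  checked <- 0
  for (rep in 1:12) {
    n <- sample(2:5, 1)
    A <- rand_panel(n, sample(6:12, 1))
    b <- pmin(1, pmax(0, as.vector(A %*% (as.vector(rmultinom(1, 20, rep(1, n))) / 20)) +
                        rnorm(nrow(A), 0, 0.08)))
    w <- rpois(nrow(A), 30) + 1
    mm <- marker_matrix(A, check = TRUE)
    lp <- fit_strain_frequencies(mm, pool_observation(b, w), solver = "lp")
    sm <- fit_strain_frequencies(mm, pool_observation(b, w), solver = "smooth")
    expect_equal(sm$objective, lp$objective, tolerance = 1e-4)
    if (lp$solver_status == "optimal") {       # unique optimum
      checked <- checked + 1
      expect_lt(max(abs(coef(lp) - coef(sm))), 1e-4)
    }
  }
  expect_gte(checked, 5)
})

test_that("weight scaling leaves the optimum unchanged; zero weights are excluded", {
  set.seed(208)
  A <- rand_panel(3, 8)
  mm <- marker_matrix(A, check = TRUE)
  b <- runif(nrow(A))
  w <- rpois(nrow(A), 30) + 1
  f1 <- fit_strain_frequencies(mm, pool_observation(b, w))
  f2 <- fit_strain_frequencies(mm, pool_observation(b, 10 * w))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)

  # a zero-coverage site carries no information: corrupting its b is harmless
  w0 <- w
  w0[1] <- 0
  b_bad <- b
  b_bad[1] <- 0
  f3 <- fit_strain_frequencies(mm, pool_observation(b_bad, w0))
  b_alt <- b
  b_alt[1] <- 1
  f4 <- fit_strain_frequencies(mm, pool_observation(b_alt, w0))
  expect_equal(coef(f3), coef(f4), tolerance = 1e-9)
  expect_equal(f3$n_effective_sites, nrow(A) - 1L)

  expect_error(fit_strain_frequencies(mm, pool_observation(b, rep(0, nrow(A)))),
               "no informative sites")
})

test_that("under-determined designs are solved but flagged", {
  A <- rbind(c(1, 0, 0), c(0, 1, 0))   # 2 informative rows, 3 taxa
  mm <- marker_matrix(A, check = TRUE)
  f <- fit_strain_frequencies(mm, pool_observation(c(0.2, 0.3), c(10, 10)))
  expect_true(f$solver_status %in% c("underdetermined", "degenerate"))
  expect_equal(sum(coef(f)), 1, tolerance = 1e-8)
})

test_that("pool frequencies align to marker coordinates, flag missing sites", {
  mm <- marker_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)), check = FALSE,
                      contig = rep("wMel_sim", 3), pos = c(100L, 200L, 300L))
  pool <- data.frame(contig = "wMel_sim", pos = c(100L, 300L),
                     ref_count = c(12L, 5L), depth = c(30L, 10L))
  obs <- call_pool_frequencies(pool, mm)
  expect_equal(obs$b, c(0.4, 0, 0.5))
  expect_equal(obs$w, c(30, 0, 10))
  expect_equal(obs$flagged, 2L)

  bad <- data.frame(contig = "chrX", pos = 100L, ref_count = 1L, depth = 2L)
  expect_error(call_pool_frequencies(bad, mm), "contig mismatch")
})

test_that("aggregation sums frequencies within coarser taxa", {
  tax <- data.frame(line = paste0("L", 1:4),
                    strain = paste0("s", 1:4),
                    clade = c("c1", "c1", "c2", "c2"),
                    superclade = "u1")
  x <- c(s1 = 0.1, s2 = 0.2, s3 = 0.3, s4 = 0.4)
  agg <- aggregate_frequencies(x, tax, "clade", from_level = "strain")
  expect_equal(agg, c(c1 = 0.3, c2 = 0.7))
  expect_equal(sum(agg), 1)
  expect_equal(unname(aggregate_frequencies(agg, tax, "superclade",
                                            from_level = "clade")), 1)
  expect_error(aggregate_frequencies(c(s9 = 1), tax, "clade",
                                     from_level = "strain"), "missing")
})

test_that("clade-level estimate agrees with aggregated strain-level estimate", {
  p <- study_panel()
  mmS <- p$matrix
  mmC <- build_marker_matrix(filter_marker_candidates(p$sites), p$taxonomy, "clade")
  x <- c(rep(4, 8), rep(3, 5)) / 47
  names(x) <- colnames(mmS$A)
  obsS <- simulate_pool(x, mmS, coverage_mean = 100, seed = 31)
  obsC <- simulate_pool(aggregate_frequencies(x, p$taxonomy, "clade",
                                              from_level = "strain"),
                        mmC, coverage_mean = 100, seed = 32)
  direct <- coef(fit_strain_frequencies(mmC, obsC))
  agg <- aggregate_frequencies(fit_strain_frequencies(mmS, obsS),
                               p$taxonomy, "clade")
  expect_lt(max(abs(direct[names(agg)] - agg)), 0.05)
})

test_that("composition recovery on simulated 30x pools stays within 0.03 MAE", {
  cfg <- sim_config()
  p <- simulate_panel(cfg, seed = 42)
  sel <- select_markers(p$matrix)$selected
  trajs <- c(simulate_trajectories(cfg, "cold", seed = 7, n_replicates = 1),
             simulate_trajectories(cfg, "hot", seed = 8, n_replicates = 1))
  xs <- do.call(rbind, lapply(trajs, identity))
  set.seed(9)
  pick <- sample(nrow(xs), 20)
  maes <- vapply(pick, function(i) {
    xt <- xs[i, ]
    obs <- simulate_pool(xt, sel, coverage_mean = 30, seed = NULL)
    mean(abs(coef(fit_strain_frequencies(sel, obs)) - xt))
  }, numeric(1))
  expect_lte(mean(maes), 0.03)
})

test_that("concordance is a per-taxon correlation over matched samples", {
  s1 <- expand.grid(replicate = c("R1", "R2"), generation = c(0, 10, 20),
                    taxon = c("A", "B"), stringsAsFactors = FALSE)
  s1$frequency <- ifelse(s1$taxon == "A", 0.2 + 0.01 * s1$generation,
                         0.8 - 0.01 * s1$generation)
  expect_equal(unname(concordance(s1, s1)), c(1, 1))

  s2 <- s1
  s2$frequency <- 1 - s1$frequency
  expect_equal(unname(concordance(s1, s2)), c(-1, -1))

  short <- s1[s1$generation == 0 & s1$replicate == "R1", ]
  expect_warning(cc <- concordance(short, short), "fewer than 3")
  expect_true(all(is.na(cc)))
})
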