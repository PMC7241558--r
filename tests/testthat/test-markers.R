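test_that("quality filter rejects sites violating single rules and keeps clean ones", {
  # 5 lines; base genotype: alt allele in 2 of 5 lines (a true subset)
  base <- c("alt", "alt", "ref", "ref", "ref")
  gt <- matrix(base, 8, 5, byrow = TRUE)
  gt[3, 1] <- "het"                           # site 3: heterozygous call
  gt[4, ] <- "alt"                            # site 4: alt in all lines
  gt[5, ] <- "ref"                            # site 5: alt in no line
  gt[6, 2] <- "miss"                          # site 6: missing genotype
  sites <- make_sites(gt)
  sites$info$qual[2] <- 35                    # site 2: QUAL below 40
  sites$info$NS[6] <- 4
  sites$info$NUMALT[7] <- 2                   # site 7: multi-allelic
  sites$info$alt[7] <- "C,T"
  sites$info$MQM[8] <- 45                     # site 8: low mapping quality

  kept <- filter_marker_candidates(sites, n_lines = 5, mean_depth = 1200)
  expect_equal(n_sites(kept), 1L)
  expect_equal(kept$info$pos, 100L)
  rej <- attr(kept, "rejections")
  expect_equal(nrow(rej), 7L)
  expect_true(any(grepl("QUAL", rej$reason)))
  expect_true(any(grepl("true non-empty subset", rej$reason)))

  # idempotence: refiltering the filtered catalogue changes nothing
  again <- filter_marker_candidates(kept, n_lines = 5, mean_depth = 1200)
  expect_equal(again$info, kept$info)
  expect_equal(again$gt, kept$gt)
  expect_equal(nrow(attr(again, "rejections")), 0L)
})

test_that("ratio guards: zero denominators reject the site, missing INFO errors", {
  gt <- matrix(c("alt", "ref", "ref"), 2, 3, byrow = TRUE)
  sites <- make_sites(gt)
  sites$info$SRR[1] <- 0
  kept <- filter_marker_candidates(sites, n_lines = 3, mean_depth = 1200)
  expect_equal(n_sites(kept), 1L)
  expect_match(attr(kept, "rejections")$reason, "zero denominator in SRF/SRR")

  sites$info$MQM <- NULL
  expect_error(filter_marker_candidates(sites, n_lines = 3),
               "configuration error.*MQM")
})

test_that("depth filter uses the precomputed per-genome mean", {
  gt <- matrix(c("alt", "ref", "ref"), 3, 3, byrow = TRUE)
  sites <- make_sites(gt, DP = c(1000, 1000, 4000))
  kept <- filter_marker_candidates(sites, n_lines = 3, mean_depth = 1000)
  expect_equal(n_sites(kept), 2L)   # 4000 >= 3 * 1000
  kept2 <- filter_marker_candidates(sites, n_lines = 3, mean_depth = 2000)
  expect_equal(n_sites(kept2), 3L)  # 4000 < 3 * 2000
})

test_that("design matrix encodes reference carriage and drops unusable sites", {
  # 2 strains (2 lines each), 3 sites: one differentiating, one constant
  # across strains, one with within-strain disagreement
  gt <- rbind(c("ref", "ref", "alt", "alt"),
              c("alt", "alt", "alt", "alt"),
              c("ref", "alt", "ref", "ref"))
  colnames(gt) <- c("L1", "L2", "L3", "L4")
  sites <- make_sites(gt)
  tax <- data.frame(line = colnames(gt),
                    strain = c("sA", "sA", "sB", "sB"),
                    clade = "c1", superclade = "u1")
  mm <- build_marker_matrix(sites, tax, level = "strain")
  expect_equal(unname(mm$A), matrix(c(1, 0), 1, 2))
  expect_equal(colnames(mm$A), c("sA", "sB"))
  expect_equal(attr(mm, "n_constant"), 1L)
  expect_equal(attr(mm, "n_inconsistent"), 1L)

  expect_error(build_marker_matrix(sites, tax[0, ], level = "strain"),
               "taxonomy")
})

test_that("multiplicity counts alternate-allele carriers", {
  mm <- marker_matrix(rbind(c(1, 0, 1, 1), c(0, 0, 1, 1)), check = TRUE)
  expect_equal(site_multiplicity(mm), c(1L, 2L))
  circ <- marker_matrix(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)), check = TRUE)
  expect_equal(site_multiplicity(circ), c(1L, 1L, 1L))
})

test_that("greedy selection: identity-style panel and irreducible panel", {
  # one private site per strain; under the partition objective one site is
  # redundant (two one-hot columns and an all-reference column still split
  # the three strains)
  ident <- marker_matrix(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)), check = TRUE)
  sel <- select_markers(ident, objective = "partition")
  expect_equal(length(sel$retained), 2L)
  expect_equal(nrow(sel$removal_log), 1L)
  expect_true(differentiates_taxa(sel$selected))

  # every site is the sole differentiator of some pair: nothing is removable
  irred <- marker_matrix(rbind(c(0, 1, 1), c(1, 0, 1)), check = TRUE)
  sel2 <- select_markers(irred, objective = "partition")
  expect_equal(length(sel2$retained), 2L)
  expect_equal(nrow(sel2$removal_log), 0L)

  # the default row-entropy objective removes nothing when all rows carry
  # equal information (all multiplicities equal)
  sel3 <- select_markers(ident, objective = "row")
  expect_equal(length(sel3$retained), 3L)

  # non-differentiating input errors before any removal
  dup <- marker_matrix(rbind(c(1, 0, 0), c(0, 1, 1)), check = TRUE)
  expect_error(select_markers(dup), "differentiate")
})

test_that("greedy selection guarantees hold on random panels", {
  set.seed(421)
  for (rep in 1:15) {
    A <- rand_panel(sample(3:5, 1), sample(6:11, 1))
    mm <- marker_matrix(A, check = TRUE)
    for (ob in c("row", "partition")) {
      sel <- select_markers(mm, objective = ob)
      # retained set still differentiates all taxa
      expect_true(differentiates_taxa(sel$selected))
      # objective trace is strictly increasing along the removal log
      if (nrow(sel$removal_log) > 1L) {
        expect_true(all(diff(sel$removal_log$score_after) > 0))
      }
      # greedy never exceeds the exhaustive multiplicity-ordered maximum
      objfun <- if (ob == "row") strainpool:::objective_row_entropy else
        strainpool:::objective_partition_entropy
      expect_lte(sel$score, oracle_selection_max(A, objfun) + 1e-9)
      # retained multiplicities stay in [1, n-1]
      expect_true(all(site_multiplicity(sel$selected) >= 1 &
                      site_multiplicity(sel$selected) <= ncol(A) - 1))
    }
  }
})

test_that("greedy selection attains the exhaustive maximum on block panels", {
  # structured panels (homogeneous multiplicity classes) are the regime the
  # selection is designed for; there the greedy matches the brute force
  p <- simulate_panel(mini_config(), seed = 11)
  A <- p$matrix$A
  expect_lte(nrow(A), 12L)
  for (ob in c("row", "partition")) {
    sel <- select_markers(p$matrix, objective = ob)
    objfun <- if (ob == "row") strainpool:::objective_row_entropy else
      strainpool:::objective_partition_entropy
    expect_equal(sel$score, oracle_selection_max(A, objfun), tolerance = 1e-12)
  }
})

test_that("selection accepts a custom objective function", {
  ident <- marker_matrix(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)), check = TRUE)
  # minimise the panel: negative size, any differentiating subset is better
  sel <- select_markers(ident, objective = function(A) -nrow(A))
  expect_equal(sel$objective, "custom")
  expect_equal(length(sel$retained), 2L)
})

test_that("marker VCF round-trips through the writer and vcfR reader", {
  p <- simulate_panel(sim_config(n_decoy_sites = 2L), seed = 3)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_marker_vcf(p$sites, path)
  back <- read_marker_vcf(path)
  expect_equal(back$info$pos, p$sites$info$pos)
  expect_equal(back$info$DP, p$sites$info$DP)
  expect_equal(back$info$qual, p$sites$info$qual)
  expect_equal(unname(back$gt), unname(p$sites$gt))
  expect_equal(colnames(back$gt), colnames(p$sites$gt))
})

test_that("marker matrix TSV round-trips", {
  p <- simulate_panel(mini_config(), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_matrix(p$matrix, path)
  back <- read_marker_matrix(path, level = "strain")
  expect_equal(back$A, p$matrix$A)
  expect_equal(back$pos, p$matrix$pos)
})
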