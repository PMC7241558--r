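#' Simulation configuration
#'
#' Returns the configuration of the synthetic study generator, with defaults
#' emulating the design of the long-term evolve-and-resequence experiment
#' this package analyses: 47 infected isofemale lines carrying 13
#' endosymbiont strains in four clades (three superclades; the first two
#' clades share one), a panel of 197 endosymbiont marker SNPs (155
#' superclade-level, 25 clade-level, 17 strain-level) plus 29 mitochondrial
#' markers (21 superclade-level), replicate populations of ~1000 transmitting
#' females, pooled sequencing at ~30x coverage, and a selection regime in
#' which the third clade ("V") carries a fitness advantage — immediately in
#' the cold environment, from generation 60 in the hot one.
#'
#' @param ... overrides for any default field.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_lines = 47L,
    clade_sizes = c(I = 4L, III = 3L, V = 4L, VI = 2L),
    superclades = list("I+III" = c("I", "III"), "V" = "V", "VI" = "VI"),
    n_superclade_sites = 155L,
    complement_fraction = 0.2,
    n_clade_sites = 25L,
    n_strain_shared_sites = 7L,
    n_decoy_sites = 20L,
    contig = "wMel_sim",
    contig_length = 1200000L,
    mt_contig = "mtDNA_sim",
    mt_contig_length = 19500L,
    n_mt_superclade_sites = 21L,
    n_mt_within_sites = 8L,
    clade_cut = 6,
    superclade_cut = 29,
    pop_size = 1000L,
    coverage_mean = 30,
    generations = seq(0L, 100L, by = 10L),
    n_replicates = 5L,
    selection = list(
      base = list(clade = NULL, fitness = 1, onset = 0L),
      cold = list(clade = "V", fitness = 1.15, onset = 0L),
      hot  = list(clade = "V", fitness = 1.15, onset = 60L)
    )
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown sim_config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (sum(cfg$clade_sizes) < 1L) stopf("clade_sizes must name at least one strain")
  fit <- vapply(cfg$selection, function(s) s$fitness, numeric(1L))
  if (any(fit <= 0)) stopf("fitness multipliers must be positive")
  structure(cfg, class = c("sim_config", "list"))
}

strain_layout <- function(config) {
  n_strains <- sum(config$clade_sizes)
  strains <- sprintf("s%02d", seq_len(n_strains))
  clade_of <- rep(names(config$clade_sizes), config$clade_sizes)
  sc_of_clade <- stats::setNames(
    rep(names(config$superclades), lengths(config$superclades)),
    unlist(config$superclades))
  missing_sc <- setdiff(names(config$clade_sizes), names(sc_of_clade))
  if (length(missing_sc)) stopf("clade(s) %s not assigned to a superclade",
                                paste(missing_sc, collapse = ", "))
  sc_of <- sc_of_clade[clade_of]
  first_of_clade <- !duplicated(clade_of)
  baseline <- first_of_clade & clade_of %in%
    names(config$clade_sizes)[config$clade_sizes >= 3L]
  list(strains = strains, clade_of = clade_of, sc_of = unname(sc_of),
       baseline = baseline, n_strains = n_strains)
}

# Alternate-allele indicator rows for the structured site classes.
panel_alt_rows <- function(config, layout) {
  n <- layout$n_strains
  rows <- list()
  class <- character()
  add <- function(carriers, cls) {
    z <- numeric(n)
    z[carriers] <- 1
    rows[[length(rows) + 1L]] <<- z
    class <<- c(class, cls)
  }

  # superclade blocks; a fraction of each block is complement-coded (alt
  # allele carried by all strains OUTSIDE the superclade), emulating sites
  # where the reference genome itself carries the rare allele — these are
  # the high-multiplicity sites the entropy selection prunes
  scs <- names(config$superclades)
  sizes <- diff(round(seq(0, config$n_superclade_sites, length.out = length(scs) + 1L)))
  for (i in seq_along(scs)) {
    carriers <- which(layout$sc_of == scs[i])
    n_comp <- floor((config$complement_fraction %||% 0) * sizes[i])
    for (k in seq_len(sizes[i])) {
      if (k > sizes[i] - n_comp) add(setdiff(seq_len(n), carriers), "superclade")
      else add(carriers, "superclade")
    }
  }

  # clade sites: alt in one clade of a multi-clade superclade
  multi <- names(config$superclades)[lengths(config$superclades) > 1L]
  sibling_clades <- unlist(config$superclades[multi], use.names = FALSE)
  if (config$n_clade_sites > 0L && !length(sibling_clades)) {
    stopf("infeasible configuration: clade-level sites need a multi-clade superclade")
  }
  if (config$n_clade_sites > 0L) {
    tgt <- rep_len(sibling_clades, config$n_clade_sites)
    for (cl in tgt) add(which(layout$clade_of == cl), "clade")
  }

  # private strain sites: one per non-baseline strain
  for (j in which(!layout$baseline)) add(j, "private")

  # shared strain sites: pairs of non-baseline strains within a clade,
  # preferring clades of singleton superclades (where they do not stretch
  # cross-clade distances past the superclade cut)
  pair_pool <- function(clades) {
    out <- list()
    for (cl in clades) {
      members <- which(layout$clade_of == cl & !layout$baseline)
      if (length(members) >= 2L && length(members) < sum(layout$clade_of == cl) + 1L) {
        prs <- utils::combn(members, 2L, simplify = FALSE)
        prs <- Filter(function(p) length(p) < sum(layout$clade_of == cl), prs)
        out <- c(out, prs)
      }
    }
    out
  }
  single_sc <- names(config$superclades)[lengths(config$superclades) == 1L]
  pool1 <- pair_pool(unlist(config$superclades[single_sc], use.names = FALSE))
  pool2 <- pair_pool(sibling_clades)
  ns <- config$n_strain_shared_sites
  if (ns > 0L) {
    if (!length(pool1) && !length(pool2)) {
      stopf("infeasible configuration: no within-clade strain pairs for shared sites")
    }
    n1 <- if (length(pool1)) min(ns, length(pool1) * (ns %/% max(1L, length(pool1)))) else 0L
    if (length(pool1) && n1 == 0L && !length(pool2)) n1 <- ns
    seq1 <- if (n1 > 0L) rep_len(pool1, n1) else list()
    rest <- ns - length(seq1)
    seq2 <- if (rest > 0L) rep_len(if (length(pool2)) pool2 else pool1, rest) else list()
    for (p in c(seq1, seq2)) add(p, "shared")
  }

  Z <- do.call(rbind, rows)
  list(Z = Z, class = class)
}

validate_panel_structure <- function(Z, layout, config) {
  n <- layout$n_strains
  if (n < 2L) stopf("infeasible configuration: cannot differentiate a single strain")
  D <- as.matrix(stats::dist(t(Z), method = "manhattan"))
  if (any(D[upper.tri(D)] == 0)) {
    stopf("infeasible configuration: identical strain genotypes")
  }
  same_clade <- outer(layout$clade_of, layout$clade_of, "==")
  same_sc <- outer(layout$sc_of, layout$sc_of, "==")
  up <- upper.tri(D)
  if (any(D[up & same_clade] > config$clade_cut)) {
    stopf("infeasible configuration: within-clade diameter exceeds the clade cut")
  }
  if (any(D[up & same_sc] > config$superclade_cut)) {
    stopf("infeasible configuration: within-superclade diameter exceeds the superclade cut")
  }
  if (any(D[up & same_sc & !same_clade] <= config$clade_cut)) {
    stopf("infeasible configuration: sibling clades are not separated at the clade cut")
  }
  if (any(D[up & !same_sc] <= config$superclade_cut)) {
    stopf("infeasible configuration: superclades are not separated at the superclade cut")
  }
  invisible(TRUE)
}

# Plausible caller INFO statistics that pass the marker filter.
draw_info_stats <- function(m, n_lines) {
  DP <- round(stats::rnorm(m, mean = n_lines * 25, sd = n_lines))
  QUAL <- round(stats::runif(m, 500, 3000), 1)
  MQM <- round(stats::runif(m, 55, 60), 2)
  MQMR <- round(MQM * stats::runif(m, 0.96, 1.04), 2)
  split2 <- function(total) {
    u <- stats::runif(m, 0.38, 0.62)
    a <- round(total * u)
    cbind(a, total - a)
  }
  rp <- split2(DP)
  sa <- split2(round(DP * 0.3))
  sr <- split2(DP - round(DP * 0.3))
  data.frame(DP = DP, NS = n_lines, NUMALT = 1, qual = QUAL,
             MQM = MQM, MQMR = MQMR,
             RPL = rp[, 1L], RPR = rp[, 2L],
             SAF = sa[, 1L], SAR = sa[, 2L],
             SRF = sr[, 1L], SRR = sr[, 2L])
}

random_alleles <- function(m) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  list(ref = ref, alt = unname(alt))
}

#' Simulate a structured marker panel with known taxonomy
#'
#' Generates a binary strain x marker panel with the clade block structure of
#' a natural endosymbiont population — superclade-, clade- and strain-level
#' (private and shared) marker sites — assigns lines to strains, and emits a
#' line-genotype catalogue (including decoy sites that fail the marker
#' filter) together with a matched mitochondrial panel whose haplotypes map
#' one-to-one onto the endosymbiont clades.  The generated panel is
#' guaranteed to differentiate all strains and to reproduce its clade /
#' superclade structure under Hamming clustering at the configured cut
#' heights; otherwise the configuration is rejected as infeasible.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the generator is a pure function of
#'   `(config, seed)`.
#' @return A list with elements `sites` (a [marker_sites()] catalogue
#'   including decoys, in genomic order), `genotypes` (clean lines x sites
#'   0/1 matrix, 1 = reference allele), `matrix` (the true strain-level
#'   [marker_matrix()]), `taxonomy` (true [assign_taxonomy()]-style mapping),
#'   `site_class` (per clean site: superclade/clade/private/shared),
#'   `mt_sites`, `mt_genotypes`, `mt_taxonomy_level` and `config`.
#' @export
simulate_panel <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  layout <- strain_layout(config)
  if (layout$n_strains < 2L) {
    stopf("infeasible configuration: cannot differentiate a single strain")
  }
  with_seed(seed, {
    pr <- panel_alt_rows(config, layout)
    validate_panel_structure(pr$Z, layout, config)
    m_clean <- nrow(pr$Z)
    perm <- sample.int(m_clean)                    # interleave site classes
    pr$Z <- pr$Z[perm, , drop = FALSE]
    pr$class <- pr$class[perm]
    n <- layout$n_strains

    # lines -> strains, near-equal occupancy
    base_n <- config$n_lines %/% n
    extra <- config$n_lines %% n
    sizes <- rep(base_n, n) + c(rep(1L, extra), rep(0L, n - extra))
    if (any(sizes == 0L)) stopf("infeasible configuration: more strains than lines")
    strain_of_line <- sample(rep(seq_len(n), sizes))
    line_ids <- sprintf("L%02d", seq_len(config$n_lines))

    taxonomy <- data.frame(line = line_ids,
                           strain = layout$strains[strain_of_line],
                           clade = layout$clade_of[strain_of_line],
                           superclade = layout$sc_of[strain_of_line],
                           stringsAsFactors = FALSE)
    class(taxonomy) <- c("taxonomy_assignment", "data.frame")

    # decoy sites: copy a clean alt pattern, then break one filter rule each
    m_decoy <- config$n_decoy_sites
    m_all <- m_clean + m_decoy
    pos_all <- sort(sample(seq_len(config$contig_length), m_all))
    shuffle <- sample(m_all)
    clean_slot <- sort(shuffle[seq_len(m_clean)])
    decoy_slot <- setdiff(seq_len(m_all), clean_slot)

    al <- random_alleles(m_all)
    info <- draw_info_stats(m_all, config$n_lines)
    info <- cbind(data.frame(contig = config$contig, pos = pos_all,
                             ref = al$ref, alt = al$alt,
                             stringsAsFactors = FALSE), info)
    gt <- matrix("ref", m_all, config$n_lines,
                 dimnames = list(NULL, line_ids))
    Zl <- pr$Z[, strain_of_line, drop = FALSE]          # clean sites x lines
    gt[clean_slot, ][Zl == 1] <- "alt"

    defect_types <- c("low_qual", "numalt", "het", "high_dp", "low_mqm",
                      "all_alt", "missing_gt")
    defects <- rep_len(defect_types, m_decoy)
    mean_dp_clean <- mean(info$DP)
    for (k in seq_len(m_decoy)) {
      i <- decoy_slot[k]
      gt[i, ] <- ifelse(pr$Z[sample(m_clean, 1L), strain_of_line] == 1, "alt", "ref")
      switch(defects[k],
        low_qual  = { info$qual[i] <- 35 },
        numalt    = { info$NUMALT[i] <- 2
                      info$alt[i] <- paste(sample(c("A", "C", "G", "T"), 2L), collapse = ",") },
        het       = { gt[i, sample(config$n_lines, 1L)] <- "het" },
        high_dp   = { info$DP[i] <- round(6 * mean_dp_clean) },
        low_mqm   = { info$MQM[i] <- 45; info$MQMR[i] <- 45 },
        all_alt   = { gt[i, ] <- "alt" },
        missing_gt = { j <- sample(config$n_lines, 1L)
                       gt[i, j] <- "miss"; info$NS[i] <- config$n_lines - 1L })
    }
    sites <- marker_sites(info, gt)

    A <- 1 - pr$Z
    rownames(A) <- site_ids(info[clean_slot, , drop = FALSE])
    colnames(A) <- layout$strains
    panel <- marker_matrix(A, level = "strain",
                           contig = info$contig[clean_slot],
                           pos = info$pos[clean_slot])

    genotypes <- t(1 - Zl)
    rownames(genotypes) <- line_ids
    colnames(genotypes) <- rownames(A)

    mt <- simulate_mt_sites(config, layout, taxonomy)

    list(sites = sites, genotypes = genotypes, matrix = panel,
         taxonomy = taxonomy, site_class = pr$class,
         mt_sites = mt$sites, mt_genotypes = mt$genotypes,
         config = config, layout = layout)
  })
}

# Mitochondrial panel: haplotypes = endosymbiont clades (strict maternal
# co-transmission); superclade blocks plus within-superclade variation.
simulate_mt_sites <- function(config, layout, taxonomy) {
  clades <- unique(layout$clade_of)
  sc_of_clade <- vapply(clades, function(cl) {
    layout$sc_of[match(cl, layout$clade_of)]
  }, character(1L))
  scs <- names(config$superclades)
  nh <- length(clades)
  rows <- list()
  sizes <- diff(round(seq(0, config$n_mt_superclade_sites,
                          length.out = length(scs) + 1L)))
  for (i in seq_along(scs)) {
    z <- as.numeric(sc_of_clade == scs[i])
    for (k in seq_len(sizes[i])) rows[[length(rows) + 1L]] <- z
  }
  multi <- names(config$superclades)[lengths(config$superclades) > 1L]
  if (config$n_mt_within_sites > 0L) {
    if (!length(multi)) stopf("infeasible configuration: mt within-superclade sites need a multi-clade superclade")
    tgt <- rep_len(unlist(config$superclades[multi], use.names = FALSE),
                   config$n_mt_within_sites)
    for (cl in tgt) rows[[length(rows) + 1L]] <- as.numeric(clades == cl)
  }
  Z <- do.call(rbind, rows)
  m <- nrow(Z)
  pos <- sort(sample(seq_len(config$mt_contig_length), m))
  al <- random_alleles(m)
  info <- cbind(data.frame(contig = config$mt_contig, pos = pos,
                           ref = al$ref, alt = al$alt, stringsAsFactors = FALSE),
                draw_info_stats(m, config$n_lines))
  hap_of_line <- match(taxonomy$clade, clades)
  Zl <- Z[, hap_of_line, drop = FALSE]
  gt <- matrix(ifelse(Zl == 1, "alt", "ref"), m, config$n_lines,
               dimnames = list(NULL, taxonomy$line))
  genotypes <- t(1 - Zl)
  rownames(genotypes) <- taxonomy$line
  colnames(genotypes) <- site_ids(info)
  list(sites = marker_sites(info, gt), genotypes = genotypes)
}

#' Write a marker catalogue as a VCF text file
#'
#' Emits a minimal VCF v4.2 with the caller INFO statistics and per-line GT
#' fields, suitable for round-tripping through [read_marker_vcf()].
#'
#' @param sites a [marker_sites()] catalogue.
#' @param path output path (plain text).
#' @export
write_marker_vcf <- function(sites, path) {
  stopifnot(inherits(sites, "marker_sites"))
  info <- sites$info
  lines_out <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(info$contig)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of samples with data\">",
    "##INFO=<ID=NUMALT,Number=1,Type=Integer,Description=\"Number of alternate alleles\">",
    "##INFO=<ID=MQM,Number=1,Type=Float,Description=\"Mean mapping quality, alt\">",
    "##INFO=<ID=MQMR,Number=1,Type=Float,Description=\"Mean mapping quality, ref\">",
    "##INFO=<ID=RPL,Number=1,Type=Float,Description=\"Reads placed left\">",
    "##INFO=<ID=RPR,Number=1,Type=Float,Description=\"Reads placed right\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads forward\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads reverse\">",
    "##INFO=<ID=SRF,Number=1,Type=Integer,Description=\"Ref reads forward\">",
    "##INFO=<ID=SRR,Number=1,Type=Integer,Description=\"Ref reads reverse\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(sites$gt)), collapse = "\t")
  )
  code <- c(ref = "0/0", alt = "1/1", het = "0/1", miss = "./.",
            other = "./.")
  gt_txt <- matrix(code[sites$gt], nrow = nrow(sites$gt))
  info_txt <- sprintf(
    "DP=%d;NS=%d;NUMALT=%d;MQM=%g;MQMR=%g;RPL=%g;RPR=%g;SAF=%g;SAR=%g;SRF=%g;SRR=%g",
    info$DP, info$NS, info$NUMALT, info$MQM, info$MQMR, info$RPL, info$RPR,
    info$SAF, info$SAR, info$SRF, info$SRR)
  recs <- paste(info$contig, info$pos, ".", info$ref, info$alt,
                format(info$qual, trim = TRUE), "PASS", info_txt, "GT",
                apply(gt_txt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines_out, recs), path)
  invisible(path)
}

per_strain_fitness <- function(selection, layout) {
  f <- rep(1, layout$n_strains)
  if (!is.null(selection$strains)) {
    f[match(selection$strains, layout$strains)] <- selection$fitness
  } else if (!is.null(selection$clade)) {
    f[layout$clade_of %in% selection$clade] <- selection$fitness
  }
  f
}

#' Simulate strain-frequency trajectories
#'
#' Wright-Fisher resampling of maternally transmitted strains with
#' regime-dependent selection: each generation, `pop_size` transmitting
#' females are drawn multinomially with probabilities proportional to the
#' current strain frequencies times the regime's fitness multipliers (applied
#' from the regime's onset generation; neutral before).
#'
#' @param config a [sim_config()].
#' @param regime `"base"`, `"cold"` or `"hot"` (must exist in
#'   `config$selection`).
#' @param seed integer seed.
#' @param x0 optional initial frequency vector (defaults to the line
#'   occupancy of the strains: lines per strain / total lines).
#' @param n_replicates,generations,pop_size optional overrides of the config.
#' @return A list of matrices (one per replicate), each `generations x
#'   strains`, rows named by sampled generation.
#' @export
simulate_trajectories <- function(config = sim_config(), regime, seed,
                                  x0 = NULL, n_replicates = NULL,
                                  generations = NULL, pop_size = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!regime %in% names(config$selection)) {
    stopf("unknown regime '%s'", regime)
  }
  layout <- strain_layout(config)
  n <- layout$n_strains
  gens <- as.integer(generations %||% config$generations)
  reps <- n_replicates %||% config$n_replicates
  N <- pop_size %||% config$pop_size
  sel <- config$selection[[regime]]
  fit <- per_strain_fitness(sel, layout)
  onset <- sel$onset %||% 0L

  if (is.null(x0)) {
    base_n <- config$n_lines %/% n
    extra <- config$n_lines %% n
    sizes <- rep(base_n, n) + c(rep(1L, extra), rep(0L, n - extra))
    x0 <- sizes / sum(sizes)
  }
  if (abs(sum(x0) - 1) > 1e-8 || any(x0 < 0)) stopf("x0 must lie on the simplex")

  with_seed(seed, lapply(seq_len(reps), function(r) {
    x <- x0
    out <- matrix(NA_real_, length(gens), n,
                  dimnames = list(gens, layout$strains))
    if (0L %in% gens) out[as.character(0L), ] <- x
    for (g in seq_len(max(gens))) {
      w <- if (g > onset) fit else rep(1, n)
      p <- x * w
      p <- p / sum(p)
      x <- as.vector(stats::rmultinom(1L, N, p)) / N
      if (g %in% gens) out[as.character(g), ] <- x
    }
    out
  }))
}

#' Simulate a pooled observation
#'
#' Pool-Seq read sampling at the marker sites: per-site depth
#' `w_i ~ Poisson(coverage_mean)` and reference read count
#' `~ Binomial(w_i, (A x)_i)`; `b_i` is the reference read fraction (0 and
#' flagged where the depth is 0).
#'
#' @param x_true true taxon frequencies on the simplex, in matrix column
#'   order (names are checked when present).
#' @param matrix a [marker_matrix()].
#' @param coverage_mean expected per-site depth.
#' @param seed integer seed (`NULL` to draw from the current RNG stream,
#'   for use inside other generators).
#' @param ... metadata passed to [pool_observation()].
#' @return A [pool_observation()].
#' @export
simulate_pool <- function(x_true, matrix, coverage_mean = 30, seed = NULL, ...) {
  stopifnot(inherits(matrix, "marker_matrix"))
  A <- matrix$A
  if (!is.null(names(x_true))) {
    if (!setequal(names(x_true), colnames(A))) {
      stopf("x_true names do not match the matrix taxa")
    }
    x_true <- x_true[colnames(A)]
  }
  if (length(x_true) != ncol(A)) stopf("x_true has wrong length")
  if (abs(sum(x_true) - 1) > 1e-8 || any(x_true < 0)) {
    stopf("x_true must lie on the simplex")
  }
  p <- as.vector(A %*% x_true)
  p <- pmin(1, pmax(0, p))
  with_seed(seed, {
    w <- stats::rpois(nrow(A), coverage_mean)
    refc <- stats::rbinom(nrow(A), w, p)
    b <- ifelse(w > 0, refc / w, 0)
    pool_observation(b, w, site_ids = rownames(A), ...)
  })
}

#' Simulate GC-biased coverage with known copy ratio
#'
#' Synthesises a target and a normalisation contig with controllable,
#' spatially varying GC composition and draws per-position depths
#' `Poisson(depth_mean * copy_ratio_if_target * bias(effective GC))`, where
#' the multiplicative bias is an arbitrary positive function of effective GC
#' shared between the two contigs — the ground truth for the GC-matched
#' copy-number estimator.
#'
#' @param length_target,length_norm contig lengths.
#' @param gc_target,gc_norm mean GC of the two contigs.
#' @param gc_amplitude amplitude of the sinusoidal GC profile (spreads
#'   positions over GC bins; the two contigs overlap in GC where their
#'   `mean +/- amplitude` ranges intersect).
#' @param copy_ratio true target : normalisation copy ratio.
#' @param bias_function positive function of effective GC.
#' @param depth_mean expected normalisation depth at bias 1.
#' @param model a [fragment_kernel()]; default single-end reads of length
#'   100.
#' @param seed integer seed.
#' @return A list with `target` and `norm` (each `seq`, `depth`, `gc`),
#'   plus the true `copy_ratio`.
#' @export
simulate_gc_coverage <- function(length_target = 1e5, length_norm = 1e5,
                                 gc_target = 0.40, gc_norm = 0.50,
                                 gc_amplitude = 0.12, copy_ratio = 5,
                                 bias_function = function(gc) 0.5 + gc,
                                 depth_mean = 30,
                                 model = fragment_kernel(c("100" = 1)),
                                 seed) {
  stopifnot(is.function(bias_function))
  make_contig <- function(len, gc_mean, ratio) {
    i <- seq_len(len)
    p <- gc_mean + gc_amplitude * sin(2 * pi * i / 10000)
    p <- pmin(0.95, pmax(0.05, p))
    is_gc <- stats::rbinom(len, 1L, p) == 1L
    s <- ifelse(is_gc, sample(c("G", "C"), len, replace = TRUE),
                sample(c("A", "T"), len, replace = TRUE))
    gc <- effective_gc(s, model)
    bias <- bias_function(gc)
    if (any(bias <= 0)) stopf("bias_function must be positive on [0, 1]")
    depth <- stats::rpois(len, depth_mean * ratio * bias)
    list(seq = paste(s, collapse = ""), depth = depth, gc = gc)
  }
  with_seed(seed, {
    list(target = make_contig(length_target, gc_target, copy_ratio),
         norm = make_contig(length_norm, gc_norm, 1),
         copy_ratio = copy_ratio)
  })
}

#' Simulate co-transmitted endosymbiont and mitochondrial pools
#'
#' Strict maternal co-transmission makes the mitochondrial superclade
#' trajectories identical to the endosymbiont ones; the two pooled
#' observations of each sample differ only through their marker panels (the
#' mitochondrial one much smaller) and independent read-sampling noise.
#'
#' @param trajectories strain-frequency trajectories from
#'   [simulate_trajectories()].
#' @param panel a [simulate_panel()] result (supplies both superclade-level
#'   design matrices and the taxonomy).
#' @param coverage_mean expected pool depth for both panels.
#' @param seed integer seed.
#' @param regime metadata tag for the emitted observations.
#' @return A data frame-driven list: `samples` (one row per replicate x
#'   generation with the true superclade frequencies) and parallel lists
#'   `wolbachia_pools`, `mtdna_pools` of [pool_observation()]s, plus the two
#'   superclade [marker_matrix()] objects `wol_matrix`, `mt_matrix`.
#' @export
simulate_cotransmission <- function(trajectories, panel, coverage_mean = 30,
                                    seed, regime = NA_character_) {
  taxonomy <- panel$taxonomy
  wol_sel <- filter_marker_candidates(panel$sites)
  wol_matrix <- build_marker_matrix(wol_sel, taxonomy, level = "superclade")
  mt_matrix <- build_marker_matrix(panel$mt_sites, taxonomy, level = "superclade")
  strain_to_sc <- unique(as.data.frame(taxonomy)[, c("strain", "superclade")])

  with_seed(seed, {
    samples <- list()
    wol_pools <- list()
    mt_pools <- list()
    for (r in seq_along(trajectories)) {
      traj <- trajectories[[r]]
      for (g in rownames(traj)) {
        x_sc <- aggregate_frequencies(stats::setNames(traj[g, ], colnames(traj)),
                                      taxonomy, "superclade",
                                      from_level = "strain")
        id <- sprintf("r%d_g%s", r, g)
        wol_pools[[id]] <- simulate_pool(x_sc, wol_matrix, coverage_mean,
                                         seed = NULL, sample_id = id,
                                         replicate = paste0("R", r),
                                         generation = as.integer(g),
                                         regime = regime)
        mt_pools[[id]] <- simulate_pool(x_sc, mt_matrix, coverage_mean,
                                        seed = NULL, sample_id = id,
                                        replicate = paste0("R", r),
                                        generation = as.integer(g),
                                        regime = regime)
        samples[[id]] <- data.frame(sample_id = id, replicate = paste0("R", r),
                                    generation = as.integer(g),
                                    taxon = names(x_sc), frequency = as.numeric(x_sc),
                                    stringsAsFactors = FALSE)
      }
    }
    list(samples = do.call(rbind, samples),
         wolbachia_pools = wol_pools, mtdna_pools = mt_pools,
         wol_matrix = wol_matrix, mt_matrix = mt_matrix)
  })
}
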