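# Shared fixtures and independent oracles, all built in code.

# A marker_sites catalogue whose INFO statistics pass every filter rule;
# per-site overrides tweak single fields to construct violations.
make_sites <- function(gt, qual = 1000, DP = 1200, NS = ncol(gt), NUMALT = 1,
                       MQM = 58, MQMR = 58, RPL = 600, RPR = 600,
                       SAF = 180, SAR = 180, SRF = 420, SRR = 420,
                       ref = "A", alt = "G", contig = "wMel_sim", pos = NULL) {
  m <- nrow(gt)
  if (is.null(colnames(gt))) colnames(gt) <- sprintf("L%02d", seq_len(ncol(gt)))
  info <- data.frame(contig = contig, pos = pos %||% seq_len(m) * 100L,
                     ref = ref, alt = alt, qual = qual,
                     DP = DP, NS = NS, NUMALT = NUMALT, MQM = MQM, MQMR = MQMR,
                     RPL = RPL, RPR = RPR, SAF = SAF, SAR = SAR,
                     SRF = SRF, SRR = SRR, stringsAsFactors = FALSE)
  marker_sites(info, gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random differentiating binary panel (sites x taxa), no constant rows.
rand_panel <- function(n_taxa, n_sites) {
  repeat {
    A <- matrix(stats::rbinom(n_sites * n_taxa, 1L, 0.5), n_sites, n_taxa)
    rs <- rowSums(A)
    A <- A[rs > 0 & rs < n_taxa, , drop = FALSE]
    if (nrow(A) >= 3L && differentiates_taxa(A)) return(A)
  }
}

# Exhaustive-search maximum of an objective over all differentiating subsets
# reachable by multiplicity-ordered admissible removals (any tie choice).
oracle_selection_max <- function(A, objfun) {
  mult <- ncol(A) - rowSums(A)
  best <- -Inf
  seen <- new.env(hash = TRUE)
  recurse <- function(retained) {
    key <- paste(which(retained), collapse = ",")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    best <<- max(best, objfun(A[retained, , drop = FALSE]))
    idx <- which(retained)
    adm <- idx[vapply(idx, function(i) {
      r <- retained; r[i] <- FALSE
      differentiates_taxa(A[r, , drop = FALSE])
    }, logical(1L))]
    if (!length(adm)) return(invisible())
    for (i in adm[mult[adm] == max(mult[adm])]) {
      r <- retained
      r[i] <- FALSE
      recurse(r)
    }
  }
  recurse(rep(TRUE, nrow(A)))
  best
}

# Exhaustive simplex grid search for the weighted-L1 optimum (step `step`).
# `localized` reports whether the grid minimum sits in a clearly separated
# basin (margin to the best point further than 3 steps away); only then does
# the grid argmin pin down the continuous optimum to within one step.
grid_search_wl1 <- function(A, b, w, step = 0.01, margin = 0.1) {
  k <- ncol(A)
  tot <- round(1 / step)
  grid <- as.matrix(expand.grid(rep(list(0:tot), k - 1L)))
  grid <- grid[rowSums(grid) <= tot, , drop = FALSE]
  X <- cbind(grid, tot - rowSums(grid)) * step
  R <- abs(X %*% t(A) - matrix(b, nrow(X), length(b), byrow = TRUE))
  obj <- as.vector(R %*% w)
  i1 <- which.min(obj)
  far <- rowSums(abs(X - matrix(X[i1, ], nrow(X), k, byrow = TRUE))) > 3 * step
  list(x = X[i1, ], objective = obj[i1],
       localized = min(obj[far]) - obj[i1] > margin)
}

# Small study-like panel: 4 strains in 2 clades (one superclade each),
# <= 12 sites, for brute-force selection checks.
mini_config <- function() {
  sim_config(n_lines = 8L,
             clade_sizes = c(A = 2L, B = 2L),
             superclades = list(A = "A", B = "B"),
             n_superclade_sites = 6L, complement_fraction = 0,
             n_clade_sites = 0L, n_strain_shared_sites = 0L,
             n_decoy_sites = 0L,
             n_mt_superclade_sites = 2L, n_mt_within_sites = 0L,
             clade_cut = 2, superclade_cut = 2.5)
}

study_panel <- function(seed = 42) simulate_panel(sim_config(), seed = seed)
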