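#' Pooled-sample marker observations
#'
#' A `pool_observation` holds, for one pooled sample, the called
#' reference-allele frequencies `b` and the coverage depths `w` at the marker
#' sites of the active design matrix, in matrix row order.  Sites without
#' pool coverage carry `w = 0` (and are flagged); they get zero weight in the
#' deconvolution.
#'
#' @param b numeric vector of reference-allele frequencies in `[0, 1]`.
#' @param w numeric vector of read depths (`>= 0`), same length as `b`.
#' @param sample_id,replicate,generation,regime optional sample metadata.
#' @param site_ids optional site identifiers.
#' @return An object of class `pool_observation`.
#' @export
pool_observation <- function(b, w, sample_id = NA_character_,
                             replicate = NA_character_, generation = NA_integer_,
                             regime = NA_character_, site_ids = NULL) {
  stopifnot(length(b) == length(w))
  if (any(w < 0)) stopf("coverage depths must be non-negative")
  if (any(b[w > 0] < 0 | b[w > 0] > 1)) stopf("frequencies must lie in [0, 1]")
  b[w == 0] <- 0
  structure(list(b = as.numeric(b), w = as.numeric(w),
                 sample_id = sample_id, replicate = replicate,
                 generation = generation, regime = regime,
                 site_ids = site_ids, flagged = which(w == 0)),
            class = "pool_observation")
}

#' @export
print.pool_observation <- function(x, ...) {
  cat(sprintf("<pool_observation> %s: %d sites (%d without coverage), mean depth %.1f\n",
              x$sample_id %||% "?", length(x$b), length(x$flagged),
              mean(x$w[x$w > 0])))
  invisible(x)
}

#' Extract pool allele frequencies at the marker sites
#'
#' Matches pooled variant calls (a table of `contig`, `pos`, `ref_count`,
#' `depth`) against the rows of a marker design matrix and returns the
#' aligned observation.  Marker sites absent from the pool calls get depth 0
#' and are flagged.
#'
#' @param pool data frame with columns `contig`, `pos`, `ref_count`, `depth`
#'   (or a path to such a TSV).
#' @param matrix a [marker_matrix()] carrying per-row `contig`/`pos`.
#' @param ... metadata passed to [pool_observation()].
#' @return A [pool_observation()] aligned to the matrix rows.
#' @export
call_pool_frequencies <- function(pool, matrix, ...) {
  stopifnot(inherits(matrix, "marker_matrix"))
  if (is.character(pool)) pool <- read_tsv_(pool)
  need <- c("contig", "pos", "ref_count", "depth")
  if (!all(need %in% names(pool))) {
    stopf("pool table must have columns %s", paste(need, collapse = ", "))
  }
  if (is.null(matrix$contig) || is.null(matrix$pos)) {
    stopf("marker matrix carries no coordinates; cannot match pool calls")
  }
  if (!any(pool$contig %in% matrix$contig)) {
    stopf("contig mismatch: pool calls share no contig with the marker catalogue")
  }
  key_m <- paste(matrix$contig, matrix$pos)
  key_p <- paste(pool$contig, pool$pos)
  i <- match(key_m, key_p)
  depth <- ifelse(is.na(i), 0, pool$depth[i])
  refc <- ifelse(is.na(i), 0, pool$ref_count[i])
  b <- ifelse(depth > 0, refc / depth, 0)
  pool_observation(b, depth, site_ids = rownames(matrix$A), ...)
}

#' Estimate strain frequencies from a pooled sample
#'
#' Fits the `n`-vector of taxon frequencies `x` for one pooled sample by
#' minimising the coverage-weighted residual of the linear mixture model
#' `A x = b` over the probability simplex:
#'
#' \deqn{\hat x = \arg\min_x \sum_i w_i\, |(Ax - b)_i| \quad
#'       \mathrm{s.t.}\; 0 \le x_j \le 1,\ \sum_j x_j = 1,}
#'
#' where `A` is the binary marker design matrix (1 = taxon carries the
#' reference allele), `b` the called reference-allele frequencies and `w` the
#' coverage depths.  The weighted-L1 objective generalises median estimation:
#' with only private markers and equal weights the optimum equals the
#' per-taxon medians of the marker frequencies (whenever those medians are
#' feasible).  The default solver is an exact linear-programming
#' reformulation; a smoothed-L1 solver and a weighted least-squares variant
#' (`norm = "l2"`, solved as a QP) are available.
#'
#' @param matrix a differentiating [marker_matrix()].
#' @param obs a [pool_observation()] aligned to the matrix rows (or a numeric
#'   vector `b`, with `weights` supplied separately).
#' @param norm `"l1"` (default) or `"l2"`.
#' @param solver for `norm = "l1"`: `"lp"` (exact, default) or `"smooth"`.
#' @param weights optional depth vector when `obs` is a plain numeric vector.
#' @return An object of class `strain_fit` with components `x` (named
#'   frequency vector on the simplex), `objective` (weighted residual at the
#'   optimum), `solver_status`, `n_effective_sites`, and residual
#'   diagnostics.  Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `simulate`.
#' @export
fit_strain_frequencies <- function(matrix, obs, norm = c("l1", "l2"),
                                   solver = c("lp", "smooth"), weights = NULL) {
  stopifnot(inherits(matrix, "marker_matrix"))
  norm <- match.arg(norm)
  solver <- match.arg(solver)
  if (!differentiates_taxa(matrix)) {
    stopf("marker matrix does not differentiate all taxa")
  }
  if (is.numeric(obs)) {
    obs <- pool_observation(obs, weights %||% rep(1, length(obs)))
  }
  stopifnot(inherits(obs, "pool_observation"))
  A <- matrix$A
  if (length(obs$b) != nrow(A)) {
    stopf("observation has %d sites but the matrix %d rows", length(obs$b), nrow(A))
  }
  keep <- obs$w > 0
  if (!any(keep)) stopf("no informative sites: all coverage weights are zero")
  Ak <- A[keep, , drop = FALSE]
  bk <- obs$b[keep]
  wk <- obs$w[keep]
  n <- ncol(A)

  res <- switch(paste(norm, if (norm == "l1") solver else "qp", sep = "."),
    "l1.lp" = wl1_simplex(Ak, bk, wk),
    "l1.smooth" = wl1_smooth(Ak, bk, wk),
    "l2.qp" = wl2_qp(Ak, bk, wk)
  )
  if (!res$status %in% c("optimal")) {
    stopf("solver failed with status '%s'", res$status)
  }
  x <- pmin(1, pmax(0, res$x))
  s <- sum(x)
  if (abs(s - 1) > 1e-6) stopf("solver returned a point far off the simplex (sum = %g)", s)
  x <- x / s
  names(x) <- colnames(A)

  status <- "optimal"
  if (sum(keep) < n) status <- "underdetermined"
  if (isTRUE(res$degenerate)) status <- "degenerate"

  r <- rep(NA_real_, nrow(A))
  r[keep] <- as.vector(Ak %*% x) - bk
  structure(list(x = x,
                 objective = if (norm == "l1") sum(wk * abs(r[keep]))
                             else sum(wk * r[keep]^2),
                 solver_status = status,
                 n_effective_sites = sum(keep),
                 residuals = r,
                 weights = obs$w,
                 b = obs$b,
                 matrix = matrix,
                 norm = norm,
                 solver = if (norm == "l1") solver else "qp",
                 level = matrix$level,
                 sample_id = obs$sample_id),
            class = "strain_fit")
}

#' @export
print.strain_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Strain-frequency fit (%s level, weighted %s, %d informative sites)\n",
              x$level, toupper(x$norm), x$n_effective_sites))
  print(round(x$x, digits))
  cat(sprintf("objective: %.4g   status: %s\n", x$objective, x$solver_status))
  invisible(x)
}

#' @export
coef.strain_fit <- function(object, ...) object$x

#' @export
fitted.strain_fit <- function(object, ...) {
  as.vector(object$matrix$A %*% object$x)
}

#' @export
residuals.strain_fit <- function(object, ...) object$residuals

#' @export
summary.strain_fit <- function(object, ...) {
  r <- object$residuals
  out <- list(x = object$x,
              level = object$level,
              norm = object$norm,
              solver_status = object$solver_status,
              n_effective_sites = object$n_effective_sites,
              objective = object$objective,
              mean_abs_residual = mean(abs(r), na.rm = TRUE),
              max_abs_residual = max(abs(r), na.rm = TRUE))
  class(out) <- "summary.strain_fit"
  out
}

#' @export
print.summary.strain_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Strain-frequency fit at the %s level (weighted %s)\n",
              x$level, toupper(x$norm)))
  cat("\nFrequencies:\n")
  print(round(x$x, digits))
  cat(sprintf("\nInformative sites: %d\nObjective: %.4g\nMean |residual|: %.4g   Max |residual|: %.4g\nStatus: %s\n",
              x$n_effective_sites, x$objective, x$mean_abs_residual,
              x$max_abs_residual, x$solver_status))
  invisible(x)
}

#' Simulate pooled observations from a fitted composition
#'
#' Draws new pooled observations at the fit's marker sites with the fitted
#' frequencies as truth: Poisson depths and binomial reference read counts
#' (see [simulate_pool()]).
#'
#' @param object a `strain_fit`.
#' @param nsim number of pools.
#' @param seed integer seed (required for reproducibility).
#' @param coverage_mean expected depth per site; default is the mean observed
#'   depth of the fit.
#' @param ... unused.
#' @return A list of [pool_observation()]s (length `nsim`).
#' @export
simulate.strain_fit <- function(object, nsim = 1, seed = NULL,
                                coverage_mean = NULL, ...) {
  cm <- coverage_mean %||% mean(object$weights[object$weights > 0])
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    simulate_pool(object$x, object$matrix, coverage_mean = cm, seed = NULL)
  }))
}

#' Aggregate frequencies to a coarser taxonomic level
#'
#' Sums taxon frequencies within the coarser taxa of a taxonomy (e.g. strains
#' within clades).  The simplex is preserved exactly.
#'
#' @param x a `strain_fit` or a named frequency vector at the finer level.
#' @param taxonomy a [taxonomy_assignment()].
#' @param to_level target level, coarser than the level of `x`.
#' @param from_level level of `x`; taken from the fit when `x` is a
#'   `strain_fit`.
#' @return Named numeric vector of frequencies at `to_level`.
#' @export
aggregate_frequencies <- function(x, taxonomy, to_level,
                                  from_level = NULL) {
  if (inherits(x, "strain_fit")) {
    from_level <- x$level
    x <- x$x
  }
  if (is.null(from_level)) stopf("`from_level` must be given for a plain vector")
  levels_order <- c(line = 1L, strain = 2L, clade = 3L, superclade = 4L)
  if (levels_order[[to_level]] <= levels_order[[from_level]]) {
    stopf("`to_level` (%s) must be coarser than the level of x (%s)",
          to_level, from_level)
  }
  tx <- as.data.frame(taxonomy)
  map <- unique(tx[, c(from_level, to_level)])
  i <- match(names(x), map[[from_level]])
  if (anyNA(i)) {
    stopf("taxa missing from taxonomy: %s",
          paste(names(x)[is.na(i)], collapse = ", "))
  }
  out <- tapply(x, map[[to_level]][i], sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  res
}

#' Concordance between two frequency time series
#'
#' Pearson correlation per taxon between two long-format frequency series
#' (e.g. endosymbiont vs mitochondrial superclade trajectories), matched on
#' replicate, generation and taxon, pooling replicates.
#'
#' @param series1,series2 data frames with columns `replicate`, `generation`,
#'   `taxon`, `frequency`.
#' @return Named numeric vector of per-taxon correlations; taxa with fewer
#'   than 3 matched points get `NA` (with a warning).
#' @export
concordance <- function(series1, series2) {
  need <- c("replicate", "generation", "taxon", "frequency")
  stopifnot(all(need %in% names(series1)), all(need %in% names(series2)))
  key <- function(d) paste(d$replicate, d$generation, d$taxon, sep = "\r")
  i <- match(key(series1), key(series2))
  matched <- !is.na(i)
  s1 <- series1[matched, , drop = FALSE]
  f2 <- series2$frequency[i[matched]]
  taxa <- unique(s1$taxon)
  out <- vapply(taxa, function(t) {
    sel <- s1$taxon == t
    if (sum(sel) < 3L) return(NA_real_)
    suppressWarnings(stats::cor(s1$frequency[sel], f2[sel]))
  }, numeric(1L))
  names(out) <- taxa
  if (anyNA(out)) {
    warning("concordance undefined for taxa with fewer than 3 matched time points: ",
            paste(taxa[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}
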