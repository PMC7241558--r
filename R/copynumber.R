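#' Fragment coverage kernel
#'
#' Builds the symmetric weight kernel used to compute effective GC content.
#' For a fragment-length law L (the insert-size distribution for paired-end
#' libraries, the read-length distribution otherwise), the kernel weight at
#' offset `d` is proportional to `E_L[max(0, L - |d|)]` — up to normalisation
#' the probability that a uniformly placed fragment covering the focal
#' position also covers the base at offset `d`.  Weights are normalised to
#' sum to 1; the kernel peaks at `d = 0`.
#'
#' @param read_length_dist probability mass over read lengths: a named
#'   numeric vector (names = lengths) or a data frame with columns `length`,
#'   `prob`.
#' @param insert_size_dist probability mass over insert sizes (same formats);
#'   required when `paired = TRUE`.
#' @param paired logical; use the insert-size law as the fragment-length law?
#' @return An object of class `fragment_model` with elements `kernel`
#'   (weights over offsets `-(Lmax-1) .. (Lmax-1)`) and `offsets`.
#' @export
fragment_kernel <- function(read_length_dist, insert_size_dist = NULL,
                            paired = FALSE) {
  as_pmf <- function(d, what) {
    if (is.data.frame(d)) d <- stats::setNames(d$prob, d$length)
    if (is.null(names(d))) stopf("%s must have lengths as names", what)
    len <- as.numeric(names(d))
    p <- as.numeric(d)
    if (any(is.na(len)) || any(len < 1) || any(len != round(len))) {
      stopf("%s has invalid lengths", what)
    }
    if (any(p < 0) || sum(p) <= 0) stopf("%s must have positive total mass", what)
    list(len = len, p = p / sum(p))
  }
  law <- if (paired) {
    if (is.null(insert_size_dist)) stopf("paired = TRUE requires an insert-size distribution")
    as_pmf(insert_size_dist, "insert-size distribution")
  } else {
    as_pmf(read_length_dist, "read-length distribution")
  }
  lmax <- max(law$len)
  offsets <- seq.int(-(lmax - 1L), lmax - 1L)
  k <- vapply(offsets, function(d) sum(law$p * pmax(0, law$len - abs(d))),
              numeric(1L))
  k <- k / sum(k)
  structure(list(kernel = k, offsets = offsets, paired = paired,
                 fragment_length = law),
            class = "fragment_model")
}

#' @export
print.fragment_model <- function(x, ...) {
  cat(sprintf("<fragment_model> kernel over offsets %d..%d (%s)\n",
              min(x$offsets), max(x$offsets),
              if (x$paired) "paired, insert-size law" else "single-end, read-length law"))
  invisible(x)
}

#' Effective GC content per reference position
#'
#' Assigns every position of a reference sequence the average GC content of a
#' DNA fragment covering it: a kernel-weighted count of G/C bases around the
#' focal position, with the kernel truncated and renormalised at the sequence
#' ends.  Ambiguous bases (N) count as non-GC but stay in the denominator
#' (fragment composition is physical; unknown bases should not inflate GC).
#'
#' @param reference_seq a character string, character vector of single bases,
#'   or a `Biostrings::DNAString`.
#' @param model a [fragment_kernel()] result.
#' @return Numeric vector of effective GC fractions in `[0, 1]`, one per
#'   position.
#' @export
effective_gc <- function(reference_seq, model) {
  stopifnot(inherits(model, "fragment_model"))
  s <- as_base_vector(reference_seq)
  gc <- as.numeric(s %in% c("G", "C", "g", "c"))
  k <- model$kernel
  half <- (length(k) - 1L) %/% 2L
  if (half == 0L) return(gc)
  np <- length(gc)
  num <- stats::convolve(gc, rev(k), type = "open")
  den <- stats::convolve(rep(1, np), rev(k), type = "open")
  idx <- (half + 1L):(half + np)
  num[idx] / den[idx]
}

as_base_vector <- function(x) {
  if (inherits(x, "DNAString") || inherits(x, "XString")) x <- as.character(x)
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L) {
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  }
  as.character(x)
}

#' GC-matched copy-number estimation
#'
#' Estimates the copy number of a target contig (endosymbiont or mtDNA)
#' relative to normalisation contigs (host autosomes) as a weighted mean over
#' effective-GC bins of the per-bin depth ratios.  Positions on both sides
#' are binned by effective GC; each bin contributes the ratio of its mean
#' target depth to its mean normalisation depth, weighted by `m*n/(m+n)`
#' where `m` and `n` are the position counts on the target and normalisation
#' side.  Bins missing either side, or with zero normalisation depth, are
#' excluded.  Because autosomes are diploid, copies per host cell default to
#' twice the depth ratio.
#'
#' @param target,norm lists or data frames with components/columns `depth`
#'   and `gc` (per-position depth and effective GC).
#' @param bin_width effective-GC bin width (default 0.01).
#' @param ploidy_factor multiplier converting the depth ratio into copies per
#'   host cell (default 2, diploid autosomal normalisation).
#' @return An object of class `copy_number_estimate` with `ratio`,
#'   `copies_per_cell`, `n_bins_used` and the per-bin table.
#' @export
estimate_copy_number <- function(target, norm, bin_width = 0.01,
                                 ploidy_factor = 2) {
  get_side <- function(x, what) {
    if (is.null(x$depth) || is.null(x$gc)) {
      stopf("%s must provide `depth` and `gc`", what)
    }
    if (length(x$depth) != length(x$gc)) stopf("%s: depth and gc differ in length", what)
    if (!length(x$depth)) stopf("%s has no positions", what)
    x
  }
  target <- get_side(target, "target")
  norm <- get_side(norm, "norm")
  stopifnot(bin_width > 0, bin_width <= 1, ploidy_factor > 0)

  bin_of <- function(gc) pmin(floor(gc / bin_width), ceiling(1 / bin_width) - 1L)
  bt <- bin_of(target$gc)
  bn <- bin_of(norm$gc)
  bins <- sort(union(unique(bt), unique(bn)))

  per_bin <- do.call(rbind, lapply(bins, function(b) {
    it <- bt == b
    im <- bn == b
    data.frame(gc_low = b * bin_width, gc_high = (b + 1) * bin_width,
               m_target = sum(it), n_norm = sum(im),
               depth_target = if (any(it)) mean(target$depth[it]) else NA_real_,
               depth_norm = if (any(im)) mean(norm$depth[im]) else NA_real_)
  }))
  per_bin$weight <- with(per_bin, ifelse(m_target > 0 & n_norm > 0,
                                         m_target * n_norm / (m_target + n_norm), 0))
  usable <- per_bin$weight > 0 & !is.na(per_bin$depth_norm) & per_bin$depth_norm > 0
  if (!any(usable)) {
    stopf("no GC overlap between target and normalization contigs")
  }
  pb <- per_bin[usable, , drop = FALSE]
  ratio <- sum(pb$weight * pb$depth_target / pb$depth_norm) / sum(pb$weight)
  structure(list(ratio = ratio,
                 copies_per_cell = ratio * ploidy_factor,
                 ploidy_factor = ploidy_factor,
                 bin_width = bin_width,
                 n_bins_used = sum(usable),
                 per_bin = per_bin),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("<copy_number_estimate> depth ratio %.3f -> %.2f copies per host cell (ploidy factor %g, %d GC bins)\n",
              x$ratio, x$copies_per_cell, x$ploidy_factor, x$n_bins_used))
  invisible(x)
}

#' Copy number from files
#'
#' Convenience wrapper: reads a reference FASTA and a per-position depth TSV
#' (`contig`, `pos`, `depth`), computes effective GC for the listed contigs
#' with the given fragment model, and runs [estimate_copy_number()].
#'
#' @param ref_fasta path to the reference FASTA.
#' @param depth a data frame or TSV path with columns `contig`, `pos`,
#'   `depth`.
#' @param target_contigs,norm_contigs contig names of the target and the
#'   normalisation side.
#' @param model a [fragment_kernel()].
#' @param ... passed to [estimate_copy_number()].
#' @return A `copy_number_estimate`.
#' @export
copy_number_from_files <- function(ref_fasta, depth, target_contigs,
                                   norm_contigs, model, ...) {
  seqs <- Biostrings::readDNAStringSet(ref_fasta)
  if (is.character(depth)) depth <- read_tsv_(depth)
  gather <- function(contigs) {
    d <- depth[depth$contig %in% contigs, , drop = FALSE]
    if (!nrow(d)) stopf("no depth records for contig(s) %s",
                        paste(contigs, collapse = ", "))
    gc <- unlist(lapply(contigs, function(ct) {
      if (!ct %in% names(seqs)) stopf("contig %s not in reference", ct)
      effective_gc(seqs[[ct]], model)
    }), use.names = FALSE)
    pos_key <- unlist(lapply(contigs, function(ct) {
      paste(ct, seq_len(Biostrings::width(seqs[names(seqs) == ct])))
    }), use.names = FALSE)
    i <- match(paste(d$contig, d$pos), pos_key)
    if (anyNA(i)) stopf("depth table has positions outside the reference")
    list(depth = d$depth, gc = gc[i])
  }
  estimate_copy_number(gather(target_contigs), gather(norm_contigs), ...)
}
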