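#' Marker site catalogues
#'
#' A `marker_sites` object holds candidate marker SNPs for a set of
#' individually sequenced isofemale lines: one row of site-level metadata per
#' SNP (coordinates, alleles, quality and the caller's INFO statistics) plus a
#' site x line genotype matrix with simplified codes `"ref"` (reference
#' homozygote), `"alt"` (alternate homozygote), `"het"` or `"miss"`.
#'
#' @param info data frame with one row per site and columns `contig`, `pos`,
#'   `ref`, `alt`, `qual` plus the INFO statistics `DP`, `NS`, `NUMALT`,
#'   `MQM`, `MQMR`, `RPL`, `RPR`, `SAF`, `SAR`, `SRF`, `SRR`.
#' @param gt character matrix (sites x lines) of simplified genotype codes;
#'   column names are line identifiers.
#' @return An object of class `marker_sites`.
#' @export
marker_sites <- function(info, gt) {
  stopifnot(is.data.frame(info), is.matrix(gt), nrow(info) == nrow(gt))
  need <- c("contig", "pos", "ref", "alt", "qual")
  miss <- setdiff(need, names(info))
  if (length(miss)) stopf("marker site table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(colnames(gt))) stopf("genotype matrix must have line ids as column names")
  bad <- setdiff(unique(as.vector(gt)), c("ref", "alt", "het", "miss", "other"))
  if (length(bad)) stopf("unknown genotype code(s): %s", paste(bad, collapse = ", "))
  structure(list(info = info, gt = gt), class = "marker_sites")
}

#' @export
print.marker_sites <- function(x, ...) {
  cat(sprintf("<marker_sites> %d sites x %d lines on contig(s) %s\n",
              nrow(x$info), ncol(x$gt),
              paste(unique(x$info$contig), collapse = ", ")))
  invisible(x)
}

#' Number of sites / lines in a catalogue
#' @param x a `marker_sites` object
#' @export
n_sites <- function(x) UseMethod("n_sites")
#' @export
n_sites.marker_sites <- function(x) nrow(x$info)

site_ids <- function(info) {
  sprintf("%s:%d:%s>%s", info$contig, as.integer(info$pos), info$ref, info$alt)
}

#' Read a per-line genotype VCF into a marker-site catalogue
#'
#' Parses a VCF (plain or bgzipped) of jointly called per-line genotypes and
#' extracts the site metadata and INFO statistics used by
#' [filter_marker_candidates()].  Multi-allelic records are kept (with
#' `NUMALT` > 1) so that the filter, not the reader, rejects them.
#'
#' @param path path to a VCF file.
#' @return A [marker_sites()] object.
#' @export
read_marker_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info_fields <- c("DP", "NS", "NUMALT", "MQM", "MQMR",
                   "RPL", "RPR", "SAF", "SAR", "SRF", "SRR")
  info <- data.frame(
    contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE
  )
  for (f in info_fields) {
    val <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = f)))
    info[[f]] <- val
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- simplify_gt(gt_raw)
  marker_sites(info, gt)
}

simplify_gt <- function(gt_raw) {
  gt <- matrix("other", nrow = nrow(gt_raw), ncol = ncol(gt_raw),
               dimnames = dimnames(gt_raw))
  norm <- gsub("|", "/", gt_raw, fixed = TRUE)
  gt[norm %in% c("0/0", "0")] <- "ref"
  gt[norm %in% c("1/1", "1")] <- "alt"
  gt[norm %in% c("0/1", "1/0")] <- "het"
  gt[is.na(norm) | norm %in% c("./.", ".")] <- "miss"
  gt
}

#' Filter candidate marker SNPs
#'
#' Applies the marker-site quality filter to a candidate catalogue: biallelic
#' SNPs only (`NUMALT == 1`, single-base alleles), fully genotyped
#' (`NS == n_lines`, no missing or heterozygous calls), `DP < 3 * mean_depth`,
#' `QUAL > 40`, `MQM > 50`, `4/5 < MQM/MQMR < 5/4`, `1/3 < RPL/RPR < 3`,
#' `1/3 < SAF/SAR < 3`, `1/3 < SRF/SRR < 3`, and the alternate allele present
#' in a true non-empty subset of the lines (at least one and at most
#' `n_lines - 1` carriers), so that every retained site discriminates among
#' lines.  The filter is idempotent.
#'
#' @param sites a [marker_sites()] catalogue.
#' @param n_lines number of lines that must be genotyped at a retained site;
#'   defaults to the number of genotype columns.
#' @param mean_depth per-genome mean of the INFO `DP` field, computed
#'   beforehand over all sites of the same genome (endosymbiont and mtDNA
#'   contigs are filtered separately); defaults to `mean(DP)` of `sites`.
#' @return The retained `marker_sites`, with a `rejections` attribute — a data
#'   frame of (site id, reason) for every rejected site.
#' @export
filter_marker_candidates <- function(sites, n_lines = ncol(sites$gt),
                                     mean_depth = NULL) {
  stopifnot(inherits(sites, "marker_sites"))
  info <- sites$info
  need <- c("DP", "NS", "NUMALT", "MQM", "MQMR",
            "RPL", "RPR", "SAF", "SAR", "SRF", "SRR")
  for (f in need) {
    if (is.null(info[[f]]) || all(is.na(info[[f]]))) {
      stopf("configuration error: INFO statistic '%s' is missing from the catalogue", f)
    }
  }
  if (is.null(mean_depth)) mean_depth <- mean(info$DP, na.rm = TRUE)

  m <- nrow(info)
  reason <- character(m)
  ratio_ok <- function(num, den, lo, hi, name) {
    bad_den <- !is.na(den) & den == 0
    ok <- !bad_den & !is.na(num) & !is.na(den) & num / den > lo & num / den < hi
    list(ok = ok, zero = bad_den, name = name)
  }
  checks <- list(
    snp  = nchar(info$ref) == 1L & nchar(info$alt) == 1L &
           info$ref %in% c("A", "C", "G", "T") & info$alt %in% c("A", "C", "G", "T"),
    numalt = !is.na(info$NUMALT) & info$NUMALT == 1,
    ns   = !is.na(info$NS) & info$NS == n_lines,
    dp   = !is.na(info$DP) & info$DP < 3 * mean_depth,
    qual = !is.na(info$qual) & info$qual > 40,
    mqm  = !is.na(info$MQM) & info$MQM > 50
  )
  labels <- c(snp = "not a biallelic SNP", numalt = "NUMALT != 1",
              ns = "NS != n_lines", dp = "DP >= 3*mean(DP)",
              qual = "QUAL <= 40", mqm = "MQM <= 50")
  for (nm in names(checks)) {
    fail <- !checks[[nm]] & reason == ""
    reason[fail] <- labels[[nm]]
  }
  for (r in list(ratio_ok(info$MQM, info$MQMR, 4 / 5, 5 / 4, "MQM/MQMR"),
                 ratio_ok(info$RPL, info$RPR, 1 / 3, 3, "RPL/RPR"),
                 ratio_ok(info$SAF, info$SAR, 1 / 3, 3, "SAF/SAR"),
                 ratio_ok(info$SRF, info$SRR, 1 / 3, 3, "SRF/SRR"))) {
    fail <- r$zero & reason == ""
    reason[fail] <- sprintf("zero denominator in %s", r$name)
    fail <- !r$ok & !r$zero & reason == ""
    reason[fail] <- sprintf("%s outside bounds", r$name)
  }
  hom <- matrix(sites$gt %in% c("ref", "alt"), nrow = m)
  fail <- !apply(hom, 1L, all) & reason == ""
  reason[fail] <- "non-homozygous or missing genotype"
  n_alt <- rowSums(sites$gt == "alt")
  fail <- !(n_alt >= 1 & n_alt <= n_lines - 1) & reason == ""
  reason[fail] <- "alt allele not in a true non-empty subset of lines"

  keep <- reason == ""
  rejections <- data.frame(site_id = site_ids(info)[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  out <- marker_sites(info[keep, , drop = FALSE],
                      sites$gt[keep, , drop = FALSE])
  attr(out, "rejections") <- rejections
  out
}

#' Binary marker design matrices
#'
#' A `marker_matrix` is the binary design matrix of the deconvolution: `m`
#' rows (marker sites, in genomic order) by `n` columns (taxa at the active
#' level), with entry 1 where the taxon carries the reference allele.
#'
#' @param A binary (0/1) matrix with site ids as row names and taxon ids as
#'   column names.
#' @param level taxonomic level of the columns (`"line"`, `"strain"`,
#'   `"clade"` or `"superclade"`).
#' @param contig,pos optional per-row coordinates (kept for pool matching).
#' @param check if `TRUE` (default) reject constant rows.
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(A, level = "strain", contig = NULL, pos = NULL,
                          check = TRUE) {
  stopifnot(is.matrix(A))
  if (!all(A %in% c(0, 1))) stopf("marker matrix entries must be 0/1")
  if (is.null(rownames(A))) rownames(A) <- sprintf("site%03d", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- sprintf("t%02d", seq_len(ncol(A)))
  rs <- rowSums(A)
  if (check && any(rs == 0 | rs == ncol(A))) {
    stopf("constant rows (all-0 or all-1) are not allowed in a marker matrix")
  }
  structure(list(A = A, level = level,
                 contig = contig, pos = pos,
                 orientation = "1 = taxon carries the reference allele"),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix> %d sites x %d taxa (level: %s)%s\n",
              nrow(x$A), ncol(x$A), x$level,
              if (differentiates_taxa(x)) ", differentiating" else ""))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$A)

#' Do the retained sites distinguish every pair of taxa?
#' @param x a `marker_matrix` (or plain binary matrix)
#' @return `TRUE` if all columns are pairwise distinct.
#' @export
differentiates_taxa <- function(x) {
  A <- if (inherits(x, "marker_matrix")) x$A else x
  if (nrow(A) == 0L) return(ncol(A) <= 1L)
  !any(duplicated(t(A)))
}

#' Build a marker design matrix at a taxonomic level
#'
#' Collapses the per-line genotypes of a filtered catalogue to taxa at the
#' requested level.  A site is usable at a level only if all member lines of
#' every taxon agree there; sites with within-taxon disagreement are dropped
#' (and counted), as are sites that become constant across taxa at that level.
#'
#' @param sites a filtered [marker_sites()] catalogue.
#' @param taxonomy a [taxonomy_assignment()] (or its data frame) mapping
#'   line ids to strain/clade/superclade; not needed for `level = "line"`.
#' @param level one of `"line"`, `"strain"`, `"clade"`, `"superclade"`.
#' @return A [marker_matrix()] with attributes `n_inconsistent` and
#'   `n_constant` (numbers of dropped sites).
#' @export
build_marker_matrix <- function(sites, taxonomy = NULL,
                                level = c("strain", "clade", "superclade", "line")) {
  stopifnot(inherits(sites, "marker_sites"))
  level <- match.arg(level)
  lines <- colnames(sites$gt)
  hom <- sites$gt %in% c("ref", "alt")
  if (!all(hom)) stopf("catalogue contains non-homozygous genotypes; filter first")
  G <- matrix(as.numeric(sites$gt == "ref"), nrow = nrow(sites$gt),
              dimnames = list(site_ids(sites$info), lines))

  if (level == "line") {
    taxon_of <- stats::setNames(lines, lines)
  } else {
    if (is.null(taxonomy)) stopf("a taxonomy is required for level '%s'", level)
    tx <- as.data.frame(taxonomy)
    if (!all(c("line", level) %in% names(tx))) {
      stopf("taxonomy lacks column '%s'", level)
    }
    taxon_of <- stats::setNames(as.character(tx[[level]]), tx$line)[lines]
    if (all(is.na(taxon_of))) stopf("taxonomy covers none of the catalogue's lines")
    if (anyNA(taxon_of)) {
      stopf("lines missing from taxonomy: %s",
            paste(lines[is.na(taxon_of)], collapse = ", "))
    }
  }
  taxa <- unique(taxon_of)
  n <- length(taxa)
  m <- nrow(G)
  A <- matrix(NA_real_, m, n, dimnames = list(rownames(G), taxa))
  consistent <- rep(TRUE, m)
  for (t in taxa) {
    sub <- G[, taxon_of == t, drop = FALSE]
    s <- rowSums(sub)
    consistent <- consistent & (s == 0 | s == ncol(sub))
    A[, t] <- as.numeric(s == ncol(sub))
  }
  rs <- rowSums(A)
  constant <- consistent & (rs == 0 | rs == n)
  keep <- consistent & !constant
  out <- marker_matrix(A[keep, , drop = FALSE], level = level,
                       contig = sites$info$contig[keep],
                       pos = sites$info$pos[keep])
  attr(out, "n_inconsistent") <- sum(!consistent)
  attr(out, "n_constant") <- sum(constant)
  out
}

#' Marker multiplicity
#'
#' The multiplicity of a marker site is the number of taxa carrying its
#' alternate (non-reference) allele, i.e. `n` minus the row sum of the design
#' matrix.  A private SNP has multiplicity 1.
#'
#' @param matrix a [marker_matrix()].
#' @return Integer vector of per-site multiplicities, in `[1, n - 1]`.
#' @export
site_multiplicity <- function(matrix) {
  stopifnot(inherits(matrix, "marker_matrix"))
  as.integer(ncol(matrix$A) - rowSums(matrix$A))
}

# --- entropy objectives -----------------------------------------------------

# Mean per-row Shannon entropy of the allele split: each retained row splits
# the n taxa into multiplicity k alt-carriers vs n-k reference carriers and
# contributes H2(k/n) bits; the objective is the mean over retained rows.
objective_row_entropy <- function(A) {
  if (nrow(A) == 0L) return(-Inf)
  k <- ncol(A) - rowSums(A)
  mean(entropy2(k / ncol(A)))
}

# Partition entropy per retained row: Shannon entropy of the partition of taxa
# into identical-column classes (uniform taxon weights) divided by the number
# of retained rows.
objective_partition_entropy <- function(A) {
  if (nrow(A) == 0L) return(-Inf)
  key <- apply(A, 2L, paste, collapse = "")
  shannon_entropy(table(key)) / nrow(A)
}

resolve_objective <- function(objective) {
  if (is.function(objective)) return(list(fn = objective, name = "custom"))
  objective <- match.arg(objective, c("row", "partition"))
  list(fn = switch(objective,
                   row = objective_row_entropy,
                   partition = objective_partition_entropy),
       name = objective)
}

#' Greedy entropy-guided marker selection
#'
#' Selects the most informative subset of marker sites that is still large
#' enough to differentiate among all taxa, by iteratively removing marker
#' sites of the currently highest multiplicity until the Shannon entropy per
#' matrix row is maximised.  At each step the candidates are the sites whose
#' removal keeps all taxon columns pairwise distinct; among those, sites of
#' maximal multiplicity are considered, ties broken by genomic order (row
#' order), and the site is removed only if the objective strictly increases.
#'
#' @param matrix a differentiating [marker_matrix()].
#' @param objective `"row"` (default: mean per-row allele-split entropy),
#'   `"partition"` (taxon-partition entropy per retained row), or a function
#'   `f(A)` returning a score to maximise.
#' @return An object of class `marker_selection` with elements `selected` (the
#'   retained [marker_matrix()]), `retained` (site ids), `score`, and
#'   `removal_log` (data frame: site id, multiplicity, score after removal).
#' @export
select_markers <- function(matrix, objective = c("row", "partition")) {
  stopifnot(inherits(matrix, "marker_matrix"))
  if (!differentiates_taxa(matrix)) {
    stopf("input matrix does not differentiate all taxa")
  }
  obj <- resolve_objective(objective)
  A <- matrix$A
  m <- nrow(A)
  n <- ncol(A)
  mult <- as.integer(n - rowSums(A))

  # pair incidence: which sites distinguish each pair of taxa
  pairs <- utils::combn(n, 2L)
  P <- matrix(FALSE, m, ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    P[, p] <- A[, pairs[1L, p]] != A[, pairs[2L, p]]
  }

  retained <- rep(TRUE, m)
  cnt <- colSums(P)                     # differentiating sites per taxon pair
  score <- obj$fn(A)
  log_rows <- list()

  repeat {
    idx <- which(retained)
    if (length(idx) <= 1L) break
    # admissible: site is not the sole differentiator of any pair
    sole <- P[idx, cnt == 1L, drop = FALSE]
    adm <- idx[rowSums(sole) == 0L]
    if (!length(adm)) break
    cand <- adm[mult[adm] == max(mult[adm])]
    best <- cand[1L]                    # genomic order tie-break
    new_retained <- retained
    new_retained[best] <- FALSE
    new_score <- obj$fn(A[new_retained, , drop = FALSE])
    if (new_score <= score + 1e-12) break
    retained <- new_retained
    cnt <- cnt - P[best, ]
    score <- new_score
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(site_id = rownames(A)[best], multiplicity = mult[best],
                 score_after = new_score, stringsAsFactors = FALSE)
  }

  removal_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(site_id = character(), multiplicity = integer(),
               score_after = numeric(), stringsAsFactors = FALSE)
  selected <- marker_matrix(A[retained, , drop = FALSE], level = matrix$level,
                            contig = matrix$contig[retained],
                            pos = matrix$pos[retained])
  structure(list(selected = selected,
                 retained = rownames(A)[retained],
                 score = score,
                 removal_log = removal_log,
                 objective = obj$name,
                 n_input = m),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf("<marker_selection> retained %d / %d sites (objective '%s' = %.4f)\n",
              length(x$retained), x$n_input, x$objective, x$score))
  invisible(x)
}

#' Write / read a marker matrix as TSV
#'
#' Rows are sites (`site_id` = `contig:pos:ref>alt`), columns taxa, cells 0/1;
#' optional `contig`/`pos` columns carry coordinates for pool matching.
#'
#' @param matrix a [marker_matrix()].
#' @param path output path.
#' @export
write_marker_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "marker_matrix"))
  df <- data.frame(site_id = rownames(matrix$A), stringsAsFactors = FALSE)
  if (!is.null(matrix$contig)) df$contig <- matrix$contig
  if (!is.null(matrix$pos)) df$pos <- matrix$pos
  df <- cbind(df, as.data.frame(matrix$A, check.names = FALSE))
  write_tsv_(df, path)
  invisible(path)
}

#' @rdname write_marker_matrix
#' @param level taxonomic level recorded in the returned object.
#' @export
read_marker_matrix <- function(path, level = "strain") {
  df <- read_tsv_(path)
  meta <- intersect(c("site_id", "contig", "pos"), names(df))
  A <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(A) <- df$site_id
  marker_matrix(A, level = level,
                contig = if ("contig" %in% meta) df$contig else NULL,
                pos = if ("pos" %in% meta) df$pos else NULL)
}

#' Write a selection report as TSV
#'
#' One row per input site: id, multiplicity, retained/removed, and for removed
#' sites the objective value after their removal (the objective trace).
#'
#' @param selection a [select_markers()] result.
#' @param matrix the input [marker_matrix()] the selection was computed from.
#' @param path output path.
#' @export
write_selection_report <- function(selection, matrix, path) {
  stopifnot(inherits(selection, "marker_selection"),
            inherits(matrix, "marker_matrix"))
  ids <- rownames(matrix$A)
  df <- data.frame(site_id = ids,
                   multiplicity = site_multiplicity(matrix),
                   status = ifelse(ids %in% selection$retained, "retained", "removed"),
                   score_after = NA_real_, stringsAsFactors = FALSE)
  if (nrow(selection$removal_log)) {
    i <- match(selection$removal_log$site_id, df$site_id)
    df$score_after[i] <- selection$removal_log$score_after
  }
  write_tsv_(df, path)
  invisible(path)
}
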