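#' Read and validate a sample sheet
#'
#' The sample sheet drives the per-sample stages of the pipeline: one row per
#' pooled sample with columns `sample_id`, `replicate`, `generation`,
#' `regime` (`hot`, `cold` or `base`), `pool_path` (a pool TSV with columns
#' `contig`, `pos`, `ref_count`, `depth`) and optionally `depth_path` (a
#' per-position depth TSV for copy-number estimation).
#'
#' @param x a data frame or a TSV path.
#' @return The validated data frame.
#' @export
read_sample_sheet <- function(x) {
  sheet <- if (is.character(x)) read_tsv_(x) else x
  need <- c("sample_id", "replicate", "generation", "regime", "pool_path")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stopf("sample sheet lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (!nrow(sheet)) stopf("sample sheet is empty")
  if (anyDuplicated(sheet$sample_id)) stopf("duplicate sample ids in sheet")
  if (any(sheet$generation < 0)) stopf("generations must be >= 0")
  bad <- setdiff(unique(sheet$regime), c("hot", "cold", "base"))
  if (length(bad)) stopf("unknown regime(s): %s", paste(bad, collapse = ", "))
  sheet
}

#' Fit a series of pooled observations
#'
#' Runs the frequency deconvolution for a list of [pool_observation()]s
#' against one design matrix and returns the long-format table behind the
#' usual trajectory figures.
#'
#' @param pools list of [pool_observation()]s (with metadata set).
#' @param matrix a differentiating [marker_matrix()].
#' @param ... passed to [fit_strain_frequencies()].
#' @return Data frame with columns `sample_id`, `replicate`, `generation`,
#'   `regime`, `level`, `taxon`, `frequency`, `objective`,
#'   `n_effective_sites`.
#' @export
fit_pool_series <- function(pools, matrix, ...) {
  rows <- lapply(pools, function(p) {
    fit <- fit_strain_frequencies(matrix, p, ...)
    data.frame(sample_id = p$sample_id, replicate = p$replicate,
               generation = p$generation, regime = p$regime,
               level = matrix$level, taxon = names(fit$x),
               frequency = as.numeric(fit$x), objective = fit$objective,
               n_effective_sites = fit$n_effective_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end: build and filter the marker catalogue
#' from a genotype VCF (or read a prebuilt marker matrix), type the lines
#' into strains/clades/superclades, select informative markers, estimate
#' frequencies for every pooled sample at the requested levels, estimate
#' copy number where depth tables are given, and write all outputs plus a
#' run manifest into `out_dir`.
#'
#' @param config a list (or YAML file path) with fields:
#'   \describe{
#'     \item{marker_vcf}{per-line genotype VCF (alternative to
#'       `marker_matrix` + `taxonomy`)}
#'     \item{marker_matrix, taxonomy}{prebuilt marker-matrix TSV and taxonomy
#'       TSV (alternative to `marker_vcf`)}
#'     \item{levels}{character vector of estimation levels (default
#'       `c("strain", "clade", "superclade")`)}
#'     \item{cuts}{Hamming cut heights, default `c(strain=0, clade=6,
#'       superclade=29)`}
#'     \item{select}{logical: apply entropy-guided marker selection per level
#'       (default TRUE)}
#'     \item{objective}{selection objective, default `"row"`}
#'     \item{norm}{deconvolution norm, default `"l1"`}
#'     \item{copy_number}{optional list: `ref_fasta`, `target_contigs`,
#'       `norm_contigs`, `read_length_dist` (named probabilities),
#'       optionally `insert_size_dist`, `paired`, `bin_width`,
#'       `ploidy_factor`}
#'   }
#' @param sample_sheet data frame or TSV path, see [read_sample_sheet()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `frequencies` (long table),
#'   `copy_numbers` (or NULL), `taxonomy`, `selections` and the manifest.
#' @export
run_pipeline <- function(config, sample_sheet, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sheet <- read_sample_sheet(sample_sheet)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  levels <- config$levels %||% c("strain", "clade", "superclade")
  cuts <- config$cuts %||% c(strain = 0, clade = 6, superclade = 29)
  do_select <- config$select %||% TRUE
  objective <- config$objective %||% "row"
  norm <- config$norm %||% "l1"

  stage <- function(name, expr) {
    message(sprintf("[strainpool] stage=%s", name))
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # -- markers & taxonomy ----------------------------------------------------
  if (!is.null(config$marker_vcf)) {
    sites <- stage("markers", {
      filter_marker_candidates(read_marker_vcf(config$marker_vcf))
    })
    typing <- stage("typing", {
      G <- matrix(as.numeric(sites$gt == "ref"), nrow = nrow(sites$gt),
                  dimnames = dimnames(sites$gt))
      type_strains(t(G), cuts = cuts,
                   clade_labels = config$clade_labels %||% NULL)
    })
    taxonomy <- typing$taxonomy
    write_dendrogram_newick(typing$tree, file.path(out_dir, "dendrogram.nwk"))
    matrices <- stage("matrices", {
      out <- lapply(levels, function(lv) build_marker_matrix(sites, taxonomy, lv))
      names(out) <- levels
      out
    })
  } else if (!is.null(config$marker_matrix)) {
    taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy) else NULL
    mm <- read_marker_matrix(config$marker_matrix,
                             level = config$marker_level %||% "strain")
    matrices <- stats::setNames(list(mm), mm$level)
    levels <- mm$level
  } else {
    stopf("config must provide either `marker_vcf` or `marker_matrix`")
  }
  write_taxonomy(taxonomy, file.path(out_dir, "taxonomy.tsv"))

  selections <- NULL
  if (isTRUE(do_select)) {
    selections <- stage("selection", {
      lapply(matrices, function(mm) select_markers(mm, objective = objective))
    })
    for (lv in names(selections)) {
      write_selection_report(selections[[lv]], matrices[[lv]],
                             file.path(out_dir, sprintf("selection_%s.tsv", lv)))
      matrices[[lv]] <- selections[[lv]]$selected
    }
  }
  for (lv in names(matrices)) {
    write_marker_matrix(matrices[[lv]],
                        file.path(out_dir, sprintf("markers_%s.tsv", lv)))
  }

  # -- per-sample frequency estimation --------------------------------------
  freq <- stage("estimation", {
    rows <- list()
    for (i in seq_len(nrow(sheet))) {
      for (lv in names(matrices)) {
        mm <- matrices[[lv]]
        obs <- tryCatch(
          call_pool_frequencies(sheet$pool_path[i], mm,
                                sample_id = sheet$sample_id[i],
                                replicate = sheet$replicate[i],
                                generation = sheet$generation[i],
                                regime = sheet$regime[i]),
          error = function(e) stopf("sample '%s': %s", sheet$sample_id[i],
                                    conditionMessage(e)))
        rows[[length(rows) + 1L]] <- fit_pool_series(list(obs), mm, norm = norm)
      }
    }
    do.call(rbind, rows)
  })
  write_tsv_(freq, file.path(out_dir, "frequencies.tsv"))

  # -- copy number -----------------------------------------------------------
  cn <- NULL
  if (!is.null(config$copy_number) && "depth_path" %in% names(sheet)) {
    cnc <- config$copy_number
    model <- fragment_kernel(unlist(cnc$read_length_dist),
                             if (!is.null(cnc$insert_size_dist))
                               unlist(cnc$insert_size_dist) else NULL,
                             paired = isTRUE(cnc$paired))
    cn <- stage("copy_number", {
      rows <- lapply(which(nzchar(sheet$depth_path %||% "")), function(i) {
        est <- copy_number_from_files(cnc$ref_fasta, sheet$depth_path[i],
                                      cnc$target_contigs, cnc$norm_contigs,
                                      model,
                                      bin_width = cnc$bin_width %||% 0.01,
                                      ploidy_factor = cnc$ploidy_factor %||% 2)
        data.frame(sample_id = sheet$sample_id[i],
                   replicate = sheet$replicate[i],
                   generation = sheet$generation[i],
                   regime = sheet$regime[i],
                   ratio = est$ratio, copies_per_cell = est$copies_per_cell,
                   n_bins_used = est$n_bins_used, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    if (!is.null(cn)) write_tsv_(cn, file.path(out_dir, "copynumber.tsv"))
  }

  manifest <- list(
    package = "strainpool",
    version = as.character(utils::packageVersion("strainpool")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_samples = nrow(sheet),
    levels = levels,
    norm = norm,
    objective = if (isTRUE(do_select)) objective else NA,
    inputs = list(sample_ids = sheet$sample_id,
                  pool_digests = vapply(sheet$pool_path, function(p)
                    unname(tools::md5sum(p)), character(1L)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(frequencies = freq, copy_numbers = cn, taxonomy = taxonomy,
                 selections = selections, manifest = manifest))
}

#' First generation at which a taxon dominates
#'
#' For each replicate of a long-format frequency table, returns the earliest
#' sampled generation at which the taxon's frequency reaches the threshold
#' (`NA` if it never does).
#'
#' @param table long-format data frame with columns `replicate`,
#'   `generation`, `taxon`, `frequency` (e.g. from [fit_pool_series()] or
#'   [run_pipeline()]).
#' @param taxon taxon of interest.
#' @param threshold dominance threshold in `[0, 1]`.
#' @return Named numeric vector, one entry per replicate (`NA` = never).
#' @export
summarize_dominance <- function(table, taxon, threshold = 0.5) {
  stopifnot(all(c("replicate", "generation", "taxon", "frequency") %in% names(table)))
  if (!taxon %in% table$taxon) stopf("taxon '%s' absent from the table", taxon)
  tb <- table[table$taxon == taxon, , drop = FALSE]
  reps <- unique(tb$replicate)
  out <- vapply(reps, function(r) {
    sub <- tb[tb$replicate == r, , drop = FALSE]
    hit <- sub$generation[sub$frequency >= threshold]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1L))
  names(out) <- reps
  out
}
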