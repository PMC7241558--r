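#' Hamming distance between genotype vectors
#'
#' @param g1,g2 equal-length binary vectors (1 = reference allele).
#' @return The number of positions at which the two vectors differ.
#' @export
hamming_distance <- function(g1, g2) {
  if (length(g1) != length(g2)) stopf("genotype vectors differ in length")
  sum(g1 != g2)
}

#' Pairwise Hamming distance matrix
#'
#' @param genotypes numeric 0/1 matrix, lines in rows, marker sites in
#'   columns; row names are line ids.
#' @return A `dist` object in Hamming units.
#' @export
hamming_matrix <- function(genotypes) {
  stopifnot(is.matrix(genotypes))
  if (!all(genotypes %in% c(0, 1))) stopf("genotypes must be binary")
  stats::dist(genotypes, method = "manhattan")
}

#' Cluster lines by Hamming distance
#'
#' Agglomerative clustering of line genotypes on the pairwise Hamming matrix.
#' With the default complete linkage a cut at height `h` bounds the
#' within-cluster Hamming diameter by `h`.
#'
#' @param genotypes lines x sites binary matrix with line ids as row names.
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return An `hclust` tree with heights in Hamming units.
#' @export
build_dendrogram <- function(genotypes,
                             linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (nrow(genotypes) < 2L) stopf("need at least two lines to cluster")
  ids <- rownames(genotypes)
  if (is.null(ids)) stopf("genotype matrix must have line ids as row names")
  if (anyDuplicated(ids)) stopf("duplicate line ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::hclust(hamming_matrix(genotypes), method = linkage)
}

#' Cut a dendrogram at a Hamming height
#'
#' Returns the partition of lines into maximal clusters whose internal merge
#' heights are at most `h`.  At `h = 0` this is the partition into identical
#' genotype vectors, i.e. the strains.
#'
#' @param tree an `hclust` tree from [build_dendrogram()].
#' @param h cut height (Hamming units), `>= 0`.
#' @return Named integer vector mapping line id to cluster index.
#' @export
cut_clusters <- function(tree, h) {
  stopifnot(inherits(tree, "hclust"), is.numeric(h), h >= 0)
  stats::cutree(tree, h = h)
}

#' Export a dendrogram to Newick
#'
#' @param tree an `hclust` tree.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Line -> strain -> clade -> superclade taxonomy
#'
#' Composes three nested partitions of the lines into a taxonomy assignment.
#' Every line must map to exactly one strain, every strain must lie inside
#' exactly one clade, and every clade inside one superclade; violations are
#' reported with the offending lines.
#'
#' @param strain_partition,clade_partition,superclade_partition named vectors
#'   (line id -> cluster) as returned by [cut_clusters()], or named character
#'   vectors of labels.
#' @param clade_labels optional named character vector (line id -> clade
#'   label, e.g. `"I"`, `"III"`, `"V"`, `"VI"`) used to name clade clusters
#'   from known member lines; clusters containing lines with conflicting
#'   labels are an error.  Superclade labels are derived by joining the labels
#'   of member clades (so clades I and III merged at the superclade cut are
#'   labelled `"I+III"`).
#' @return An object of class `taxonomy_assignment`: a data frame with
#'   columns `line`, `strain`, `clade`, `superclade`.
#' @export
assign_taxonomy <- function(strain_partition, clade_partition,
                            superclade_partition, clade_labels = NULL) {
  lines <- names(strain_partition)
  if (is.null(lines)) stopf("partitions must be named by line id")
  if (!identical(sort(lines), sort(names(clade_partition))) ||
      !identical(sort(lines), sort(names(superclade_partition)))) {
    stopf("partitions cover different line sets")
  }
  clade_partition <- clade_partition[lines]
  superclade_partition <- superclade_partition[lines]

  check_nested <- function(fine, coarse, what) {
    for (g in unique(fine)) {
      member <- names(fine)[fine == g]
      if (length(unique(coarse[member])) > 1L) {
        stopf("partitions are not nested: %s '%s' spans several %s (lines %s)",
              what[1L], g, what[2L], paste(member, collapse = ", "))
      }
    }
  }
  check_nested(strain_partition, clade_partition, c("strain", "clades"))
  check_nested(clade_partition, superclade_partition, c("clade", "superclades"))

  label_of <- function(partition, prefix) {
    ord <- unique(partition)
    stats::setNames(sprintf("%s%02d", prefix, seq_along(ord)), ord)[as.character(partition)]
  }
  strain <- label_of(strain_partition, "s")
  clade <- label_of(clade_partition, "c")
  if (!is.null(clade_labels)) {
    lab <- vapply(unique(clade_partition), function(g) {
      member <- lines[clade_partition == g]
      known <- unique(stats::na.omit(clade_labels[member]))
      if (length(known) > 1L) {
        stopf("conflicting clade labels within one cluster: %s",
              paste(known, collapse = ", "))
      }
      if (length(known) == 1L) known else NA_character_
    }, character(1L))
    names(lab) <- unique(clade_partition)
    got <- !is.na(lab[as.character(clade_partition)])
    clade[got] <- lab[as.character(clade_partition)][got]
  }
  superclade <- vapply(unique(superclade_partition), function(g) {
    member <- lines[superclade_partition == g]
    paste(sort(unique(clade[match(member, lines)])), collapse = "+")
  }, character(1L))
  names(superclade) <- unique(superclade_partition)
  out <- data.frame(line = lines,
                    strain = unname(strain),
                    clade = unname(clade),
                    superclade = unname(superclade[as.character(superclade_partition)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_assignment", "data.frame")
  out
}

#' @export
print.taxonomy_assignment <- function(x, ...) {
  cat(sprintf("<taxonomy_assignment> %d lines, %d strains, %d clades, %d superclades\n",
              nrow(x), length(unique(x$strain)), length(unique(x$clade)),
              length(unique(x$superclade))))
  invisible(x)
}

#' Type lines into strains, clades and superclades
#'
#' One-call wrapper: clusters the line genotypes by Hamming distance and cuts
#' the tree at the strain, clade and superclade heights.  The defaults (0, 6,
#' 29) define strains as identical marker genotypes, clades as clusters of
#' diameter at most 6 differences, and superclades at 29.
#'
#' @param genotypes lines x sites binary matrix (1 = reference allele).
#' @param cuts numeric vector `c(strain=, clade=, superclade=)` of Hamming cut
#'   heights.
#' @param linkage linkage method, see [build_dendrogram()].
#' @param clade_labels optional, see [assign_taxonomy()].
#' @return A list with `tree` (`hclust`) and `taxonomy`
#'   ([assign_taxonomy()] result).
#' @export
type_strains <- function(genotypes, cuts = c(strain = 0, clade = 6, superclade = 29),
                         linkage = "complete", clade_labels = NULL) {
  tree <- build_dendrogram(genotypes, linkage = linkage)
  taxonomy <- assign_taxonomy(cut_clusters(tree, cuts[["strain"]]),
                              cut_clusters(tree, cuts[["clade"]]),
                              cut_clusters(tree, cuts[["superclade"]]),
                              clade_labels = clade_labels)
  list(tree = tree, taxonomy = taxonomy)
}

#' Count strains with private SNPs
#'
#' A strain has a private SNP if it is the sole alternate-allele carrier at
#' one or more sites of the strain-level marker matrix.
#'
#' @param matrix a strain-level [marker_matrix()].
#' @return Number of strains with at least one private site.
#' @export
count_private_strains <- function(matrix) {
  stopifnot(inherits(matrix, "marker_matrix"))
  A <- matrix$A
  private_rows <- rowSums(A) == ncol(A) - 1L
  if (!any(private_rows)) return(0L)
  sum(colSums(A[private_rows, , drop = FALSE] == 0) > 0L)
}

#' Write a taxonomy as TSV
#' @param taxonomy a [assign_taxonomy()] result.
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write_tsv_(as.data.frame(taxonomy), path)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  out <- read_tsv_(path)
  if (!all(c("line", "strain", "clade", "superclade") %in% names(out))) {
    stopf("taxonomy file must have columns line, strain, clade, superclade")
  }
  class(out) <- c("taxonomy_assignment", "data.frame")
  out
}
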