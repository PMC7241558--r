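Package: strainpool
Title: Endosymbiont Strain-Frequency Deconvolution and Copy-Number
    Estimation from Pool-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking Wolbachia (and other maternally transmitted
    endosymbiont) strain dynamics in evolve-and-resequence experiments on
    pooled sequencing data.  Builds catalogues of strain-discriminating
    marker SNPs from per-line genotype VCFs, selects an informative marker
    subset by a Shannon-entropy criterion, types isofemale lines into
    strains, clades and superclades by Hamming-distance clustering,
    estimates strain frequencies in pooled samples by constrained
    coverage-weighted L1 minimisation on the marker design matrix, and
    estimates endosymbiont and mitochondrial copy number per host cell from
    relative coverage depth with GC-matching bias correction.  A synthetic
    data generator produces marker panels, Wright-Fisher strain-frequency
    trajectories, binomially resampled pooled observations and GC-biased
    coverage with known ground truth, so the whole pipeline is testable
    without raw reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    ape,
    quadprog,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
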