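---
title: "Methods: strain deconvolution and copy-number estimation from Pool-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain deconvolution and copy-number estimation from Pool-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainpool)
```

# The problem

A *Drosophila* population founded from wild-caught isofemale lines can carry
many *Wolbachia* strains at once.  Because *Wolbachia* and mitochondria are
co-transmitted through the female germline, the strain composition of an
evolving population drifts and responds to selection, and pooled whole-genome
sequencing (Pool-Seq) of flies at successive generations records that
composition indirectly: every read covering a strain-discriminating SNP is a
vote for the strains compatible with its allele.  `strainpool` turns those
votes into strain, clade and superclade frequency trajectories, and estimates
endosymbiont titre (genome copies per host cell) from relative coverage
depth.

# Marker catalogue

Markers are biallelic SNPs called jointly across the individually sequenced
founder lines.  `filter_marker_candidates()` retains sites that are fully
genotyped and homozygous in every line, well supported (`QUAL > 40`,
`MQM > 50`, `DP < 3 x mean(DP)` with the mean depth precomputed per genome —
endosymbiont and mtDNA contigs separately), balanced in mapping and strand
statistics (`4/5 < MQM/MQMR < 5/4`, and `RPL/RPR`, `SAF/SAR`, `SRF/SRR` all
within `(1/3, 3)`), and polymorphic in the informative sense: the alternate
allele must occur in a true non-empty subset of the lines, because a site
fixed either way cannot separate strains.  Sites with a zero denominator in
any ratio are rejected (with a logged reason) rather than imputed; a missing
INFO statistic is a configuration error, since silently skipping a rule
would change the catalogue's meaning.  The filter is idempotent.

`build_marker_matrix()` collapses line genotypes to taxa at a chosen level.
The design matrix `A` has one row per usable site and one column per taxon,
with 1 meaning "the taxon carries the *reference* allele".  A site is usable
at a level only if all member lines of every taxon agree there; sites
varying within a taxon are informative about a finer level only and are
dropped (and counted), as are sites constant across all taxa.  This is why
the clade-level matrix is a strict subset of the strain-level one, and the
superclade-level matrix a subset again.

## Entropy-guided marker selection

Not all markers are equally informative: a SNP shared by most strains mostly
measures the reference-like fraction, while a private SNP measures one
strain directly.  `select_markers()` prunes the catalogue by iteratively
removing sites of the currently highest multiplicity (number of
alternate-allele carriers) for as long as this strictly increases a Shannon
information score per retained row, under the hard constraint that the
retained rows keep all taxon columns pairwise distinct.  Ties within a
multiplicity class are broken by genomic order, which makes the procedure
deterministic and reproducible.

Two scores are provided, and the objective is pluggable:

* **`"row"` (default)** — the mean over retained rows of the binary entropy
  `H2(k/n)` of the allele split the row induces (multiplicity `k` of `n`
  taxa).  At three taxa every possible row has the same entropy
  (`H2(1/3) = H2(2/3)`), so at the superclade level no removal can improve
  the mean and the whole superclade catalogue is retained — which is the
  observed behaviour of this selection on real panels.  At finer levels the
  score prunes the very-high-multiplicity rows, whose splits are nearly
  degenerate.
* **`"partition"`** — the Shannon entropy of the partition of taxa into
  identical-column classes, divided by the number of retained rows.  While
  the retained set differentiates all taxa this is `log2(n) / |S|`, so the
  greedy walks towards a minimal differentiating subset.  It is kept as an
  explicit alternative because it makes "information per retained site"
  literal, but it is not the default precisely because it never retains
  redundant rows, and redundancy is what averages out read-sampling noise.

A caveat worth recording: no single-path greedy of this family attains, on
every panel, the maximum of the score over *all* subsets reachable by
multiplicity-ordered removals — tie-break choices within a multiplicity
class can open or close later removals.  On block-structured panels (private
/ clade / superclade site classes, homogeneous multiplicity within class)
the greedy does attain the exhaustive maximum, and the test suite checks
exactly that, alongside the unconditional guarantees (differentiation is
never lost; the score trace is strictly increasing).

# Strain typing

Lines are clustered by the Hamming distance between their binary marker
genotypes (`stats::hclust` on a Manhattan distance of 0/1 vectors).
Complete linkage is the default because a cut at height `h` then bounds the
within-cluster genotype diameter by `h` differences, which is the natural
reading of "clusters at `h`"; average and single linkage are selectable, and
well-separated groups give the same partitions under any of them.  The three
standard cuts are:

* `h = 0` — strains: groups of identical marker genotypes;
* `h = 6` — clades: tight clusters a handful of differences wide;
* `h = 29` — superclades: the major groups (in the motivating system, two
  clades merge at this height into one superclade).

`assign_taxonomy()` composes the three cuts into a line → strain → clade →
superclade map, verifying nestedness (cuts of the same tree are always
nested; independently supplied partitions may not be).  Clade *names* are a
nomenclature, not a computation: a small user-supplied map from known member
lines labels the clusters, and superclade labels are joins of their member
clades' labels.

# Frequency deconvolution

For a pooled sample with reference-allele frequencies `b` and coverage
depths `w` at the `m` retained marker sites, the taxon frequency vector `x`
solves

$$\hat x \;=\; \arg\min_{x}\ \sum_{i=1}^{m} w_i\,\lvert (Ax-b)_i\rvert
\qquad\text{s.t.}\quad 0 \le x_j \le 1,\ \ \sum_j x_j = 1 .$$

The L1 norm is the point: with only sites that each measure a single taxon
and equal weights, the optimum is exactly the per-taxon *median* of the site
frequencies (the median minimises mean absolute deviation), so the estimator
inherits the median's robustness to outlying sites — a mismapped or
copy-number-variable marker shifts the estimate far less than it would a
least-squares fit.  Coverage weighting lets well-covered sites speak with
their read support.  A weighted least-squares variant (`norm = "l2"`,
solved exactly as a QP) is provided for comparison but is not the default.

## Solvers and numerical choices

* The reference solver is an **exact linear program**: residuals are split
  as `r = u - v` with `u, v >= 0`, giving `m + 1` equality constraints in
  `n + 2m` variables, solved by a dense primal simplex written for this
  package.  A basic feasible start needs no artificial variables (one pivot
  puts `x_1` into the simplex-sum row; each residual row is then basic in
  `u_i` or `v_i` by the sign of its right-hand side).  Dantzig pricing with
  a Bland fallback guards against cycling.  Problem sizes here (`m` up to a
  few hundred, `n` up to ~13) solve in milliseconds.
* A **smoothed-L1** solver (graduated `sqrt(r^2 + eps)` smoothing, `eps`
  from 1e-4 down to 1e-12, minimised by projected gradient descent with
  backtracking on the simplex) serves as an independent cross-check; the
  smoothed objective is convex in `x`, so it cannot be trapped away from
  the global optimum.  Tests require LP/smooth agreement to 1e-4 per
  component on instances with a unique optimum.
* The feasible set uses **closed** bounds `[0, 1]`: an open simplex has no
  attained minimum in degenerate cases, and the closed optimum is what the
  open formulation approaches anyway.
* **Non-uniqueness** is flagged, not averaged: weighted-L1 fits can have
  flat optimal edges (ties between residual sign patterns).  The LP detects
  them through zero reduced costs on nonbasic columns and reports
  `solver_status = "degenerate"` while returning its vertex solution, so
  runs are reproducible.  Under-determined inputs (fewer informative sites
  than taxa) are solved and flagged `"underdetermined"`.
* **Zero-coverage sites** get weight zero and are excluded (never imputed);
  if all weights vanish the fit errors out.
* Returned frequencies are clipped to `[0, 1]` and renormalised; the sum is
  verified to be within 1e-6 of 1 before cleaning and the object invariant
  afterwards is `sum(x) = 1` to 1e-8.

Frequencies at coarser levels can be estimated directly from the coarser
design matrix or by summing a finer fit (`aggregate_frequencies()`); the two
agree within sampling noise, which the tests check at high coverage.

# Copy number with GC matching

Endosymbiont titre is estimated as sequencing depth on the target contig
relative to host autosomes.  Because library preparation biases depth as a
function of local GC content — and an AT-rich endosymbiont genome sits in a
different GC regime than its host — raw depth ratios are biased.  The
correction matches positions of like *effective GC*:

1. `fragment_kernel()` builds a weight kernel over offsets `d` with
   `k(d) ∝ E_L[max(0, L - |d|)]`, the probability (up to normalisation)
   that a uniformly placed fragment of random length `L` covering the focal
   base also covers offset `d`.  The fragment-length law is the insert-size
   distribution for paired-end data and the read-length distribution
   otherwise; the full insert is used, since both mates' fragment is one
   molecule during amplification.
2. `effective_gc()` convolves the 0/1 GC indicator of the reference with
   the kernel (truncated and renormalised at contig ends).  Ambiguous bases
   count as non-GC but stay in the denominator: fragment composition is
   physical, and unknown bases should not inflate GC.
3. `estimate_copy_number()` bins positions by effective GC (bin width 0.01
   by default — fine enough to track realistic bias slopes, coarse enough
   to populate bins on a megabase-scale genome), forms the per-bin ratio of
   mean target to mean normalisation depth, and averages ratios with
   weights `m·n/(m+n)` (the harmonic pairing of the position counts on the
   two sides, so a bin is only as influential as its thinner side).  Bins
   missing either side or with zero normalisation depth are excluded; if no
   bin is usable the GC ranges simply do not overlap and the estimate is
   refused.

Any multiplicative bias that is a function of effective GC alone cancels in
the per-bin ratios, which is the property the simulation-based tests verify.
The depth ratio is converted to **copies per host cell** by a configurable
`ploidy_factor` (default 2: the autosomal normalisation is diploid, the
endosymbiont genome is counted per cell).  The factor is reported alongside
the raw ratio, since "per cell" conventions vary.  Per-position depth tables
are the core input; computing them from alignments (after the usual
proper-pair, mapping-quality and duplicate filters) is adapter territory and
outside the package core.

# The synthetic data generator

`sim_config()` fixes the simulated study design; its defaults emulate the
motivating experiment:

| field | default | emulates |
|---|---|---|
| `n_lines` | 47 | infected founder isofemale lines |
| `clade_sizes` | I:4, III:3, V:4, VI:2 (13 strains) | strains per clade |
| `superclades` | I+III merged; V; VI | superclade structure |
| `n_superclade_sites` | 155 | superclade-differentiating SNPs |
| `n_clade_sites` | 25 | clade-only SNPs (155 + 25 = 180 clade-differentiating) |
| private + `n_strain_shared_sites` | 10 + 7 | strain-level SNPs (197 total) |
| `complement_fraction` | 0.2 | sites where the reference carries the rare allele (high multiplicity) |
| mtDNA sites | 21 superclade + 8 within (29) | the smaller mtDNA marker set |
| `pop_size` | 1000 | transmitting females per replicate |
| `coverage_mean` | 30 | pool depth per site |
| `generations` | 0–100 by 10 | sampling time points |
| `selection` | clade V fitness 1.15; onset 0 (cold) / 60 (hot) | replace-and-dominate dynamics |

`simulate_panel()` constructs the binary strain × site panel from those
block sizes, assigns lines to strains, attaches caller-plausible INFO
statistics, plants decoy sites that each violate one filter rule, and
*validates* the geometry: strains distinct, within-clade diameter at most
the clade cut, sibling clades separated, superclades separated beyond the
superclade cut.  Infeasible configurations error rather than silently
producing a panel with different structure.  Strain frequencies evolve by
Wright–Fisher multinomial resampling of maternal transmitters with
regime-dependent fitness (`simulate_trajectories()`); pooled observations
draw Poisson depths and binomial reference counts (`simulate_pool()`);
GC-biased coverage shares one bias function between target and
normalisation contigs (`simulate_gc_coverage()`); and
`simulate_cotransmission()` emits paired endosymbiont/mtDNA pools from the
same underlying trajectories, differing only in panel size and independent
read noise.  Every generator is a pure function of `(config, seed)`.

**What passing tests do and do not show.**  The generator reproduces the
*structure* of a real founder panel (block architecture, catalogue counts,
cluster geometry) and the *sampling laws* of Pool-Seq (Poisson × binomial),
but not everything real data does: no mapping artefacts or reference bias at
marker sites, no copy-number variation among strains feeding back into pool
allele frequencies, no contamination, clonal lines without residual
heterozygosity, and selection coefficients that are constant per regime
after onset.  Tests passing on this generator validate the machinery —
filters, clustering, the optimiser, the GC matching — under the stated
models, not the biological conclusions one would draw from any particular
real data set.

Two deliberate reading choices are documented here rather than hidden in
code.  First, the greedy's information score (see above): the per-row mean
entropy is the default because it is the reading under which a
superclade-level catalogue is retained in full.  Second, recovery accuracy
is quoted for pooled samples of the simulated *experiment* (compositions
visited by the trajectories, including the founder composition), because
those are the samples the design produces.  At a near-uniform 13-strain
composition the per-strain error at 30x coverage is larger (~0.04): the
panel's printed structure implies only 17 sites resolve strains within
clades, so closely related strains at low individual frequency are
genuinely hard to separate at that depth — more coverage, not more
machinery, is the remedy.

# Problem sizes used in tests

The suite runs entirely on synthetic data built at test time: panels of
197 × 13 (and minimal 10 × 4 panels for brute-force selection oracles),
pools at 30x over up to 197 sites, grid-search deconvolution oracles at step
0.01 on 4 taxa, GC-bias simulations on 50–100 kb contigs, and end-to-end
runs with 2–3 replicates over 11 time points.  These sizes keep every oracle
exhaustive or near-exhaustive while exercising the same code paths a full
study would.

# Known limitations

* Marker frequencies say nothing about the *fraction of infected hosts*;
  the composition `x` is a distribution over strains among transmitted
  symbiont copies at the marker sites.
* L1 optima can be non-unique on small or degenerate designs; the flagged
  vertex solution is reproducible but not canonical.
* The greedy selection is a heuristic: optimal within its removal family on
  block-structured panels, not in general.
* Copy-number estimates are relative to the normalisation contigs; absolute
  titre comparisons across libraries assume the normalisation side is
  copy-stable.
* Clade naming requires external anchors (known member lines); the package
  computes partitions, not nomenclature.

# A worked example

```{r example}
cfg <- sim_config()
panel <- simulate_panel(cfg, seed = 42)
sel <- select_markers(panel$matrix)
sel

x_true <- setNames(c(rep(4, 8), rep(3, 5)) / 47, colnames(panel$matrix$A))
obs <- simulate_pool(x_true, sel$selected, coverage_mean = 30, seed = 1)
fit <- fit_strain_frequencies(sel$selected, obs)
summary(fit)

round(aggregate_frequencies(fit, panel$taxonomy, "clade"), 3)
```
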