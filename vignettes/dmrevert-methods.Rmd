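---
title: "Methods: tracking gain and loss of drug resistance through DNA methylation"
author: "dmrevert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking gain and loss of drug resistance through DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrevert)
```

## The experimental design this package models

`dmrevert` analyses a four-state cell-culture design used to study
reversible drug resistance: **parental** cells, **resistant** cells
derived from them by prolonged inhibitor exposure, and two
drug-withdrawal states sampled after five (**P5**) and twelve (**P12**)
passages without drug. Whole-genome bisulfite sequencing of two cell
lines provides per-CpG methylation levels for every state; whole-genome
sequencing provides variant allele fractions (VAFs); RNA-seq provides
gene-level log2 fold changes; and viability assays provide dose-response
matrices for the primary inhibitor and an epigenetic drug.

The package asks, on each data type, the same question: *which changes
acquired with resistance are undone after drug withdrawal, and which
persist?* Methylation changes largely revert; the mutational genotype of
the expanded resistant clone persists. That asymmetry is the scientific
signal every module here quantifies.

## DMR detection

A differentially methylated region (DMR) is a run of at least
`min_cpgs = 4` consecutive CpGs whose methylation differs between
parental and resistant states by at least `min_delta = 0.4` **in both
cell lines**, with a consistent direction.

Raw per-CpG levels at ~30x coverage are too noisy to threshold directly,
so levels are smoothed over a small CpG-count window first. Two
semantics are provided (`dmr_call_params(delta_mode = ...)`):

* **`region_mean`** (default). Candidate CpGs are those whose
  *running-median*-smoothed difference (window 5 CpGs) exceeds
  `candidate_delta = 0.2` with the same sign in every line; maximal
  same-sign candidate runs are then kept when they contain `min_cpgs`
  CpGs and the per-line mean of the *raw* differences over the run
  reaches `min_delta`. This mirrors the canonical bsseq-style workflow,
  where candidate regions from a smoothed-statistic cutoff are filtered
  by CpG count and region mean difference (`n & meanDiff`).
* **`per_cpg`**. The running-mean smoothed difference must clear
  `min_delta` at every single CpG of the run.

The median smoother is the deliberate choice for candidate detection: a
running mean attenuates every region edge (an edge CpG of a 4-CpG region
averages mostly flanking background, so with a true shift of 0.5 its
smoothed difference falls below 0.4 even without noise, and a 4-CpG
region can then never be called). A running median keeps the full shift
at any CpG whose window majority lies inside the region, so regions down
to the 4-CpG minimum remain callable. `candidate_delta` is kept
independent of `min_delta` so that relaxing `min_delta` only admits more
regions and never re-segments candidate runs (monotonicity).

`smooth_methylation()` exposes the coverage-weighted running mean as a
general utility; `call_dmrs()` applies the machinery above, inner-joins
the CpG universes of all tracks, drops CpGs below `min_coverage`, and
attaches per-line, per-state mean methylation to every DMR. Qualifying
runs separated by a single non-qualifying CpG are *not* merged.

On synthetic data at the study's conditions (true shift 0.5, 4-30 CpG
regions, 30x coverage, two lines), the default caller recovers planted
regions with precision 1.0 and recall 0.94-0.98 (see
`tests/testthat/test-acceptance.R`).

## Reversion scoring

For a DMR with parental, resistant and P12 means `m_P`, `m_R`, `m_P12`,
let `d1 = m_R - m_P` be the acquired shift and `d2 = m_P12 - m_R` the
post-withdrawal change. The reversion score is

```
score = clamp(-d2 / d1, 0, 1)
```

the fraction of the acquired shift undone at P12: 0 when P12 stayed at
the resistant level (or drifted further), 1 when it reached or overshot
the parental level, and strictly between otherwise. The score is
symmetric under hyper/hypo exchange and satisfies `score > 0.5` exactly
when the P12 level is closer to parental than to resistant — the
defining property of a "reverting" region. The score is undefined (an
error) when `m_R = m_P`, i.e. for a region that was never differential.

Per-DMR scores are the arithmetic mean of per-line scores. The
*reverting* flag is assigned by an empirical-quantile rule
(`classify_reverting_dmrs()`): the cutoff is the `quantile_cutoff = 0.90`
quantile of all scores and DMRs strictly above it are flagged, so close
to 10% of DMRs are flagged by construction and the cutoff value is
reported alongside. `p5_intermediacy()` checks the companion
observation that the P5 state, with its intermediate phenotype, sits
between the resistant and P12 levels (inclusive, all lines in
agreement).

For transcripts, `expression_reversion_score()` implements a piecewise
ratio on `log2FC(P, R)` and `log2FC(P12, R)`: 0 when the parental
change is small (`|log2FC(P, R)| < 1`) or the two changes disagree in
sign, else `max(|.|,|.|)/min(|.|,|.|)` (denominator floored at
`score_floor`). A value near 1 means P12 mirrors the parental
expression change; no flagging cutoff is imposed because none is
defined for transcripts — raw scores are returned.

## Genomic context

`build_cpg_context()` partitions each chromosome by distance to CpG
islands: shores reach 2000 bp from an island, shelves 2000 bp from a
shore, the ocean is everything else; precedence island > shore > shelf
makes the four sets an exact partition. `build_gene_context()` does the
same for exon/intron/intergenic with exon precedence. Compositions are
measured in bp (`annotate_region_context()`) and compared against the
genome-wide background with a Pearson chi-square on bp counts
(`composition_chisq()`). Strand is ignored throughout; TSS positions
are taken strand-aware from the gene records when the models are built.
`nearest_flanking_genes()` reports the closest TSS on each side of a
region (distance 0 inside; ties broken by coordinate then gene id), and
`label_expression_change()` applies the strict `|log2FC| > 1` up/down
rule.

## Feature enrichment against matched random regions

`enrichment_test()` compares how often the regions of interest overlap a
feature track with how often length- and CpG-matched random regions do.
Per iteration every region is replaced by one rejection-sampled random
region whose length is within 10% and whose CpG count is within
max(1, 10%) of its template ("similar length and CpG count"); the
feature-overlapping-region count of each random replicate set is
compared with the observed count. A feature is enriched at level *l*
when the observed count strictly exceeds the random one in at least
`1 - l` of iterations (levels 0.05 / 0.01 / 0.001). The default
`n_iterations = 1e4` is desk scale; the study-scale 1e6 is a parameter.
Random regions may overlap each other and the originals.
`enrichment_panel()` forks a deterministic per-track random stream from
the base seed and each track's rank in alphabetical order, so results
are independent of the order in which tracks are supplied.

## Clonality from VAF trajectories

Variants are classified from their parental-to-resistant VAF change
(`classify_variants()`): **VpP** (present in parental, VAF drops to 0),
**VpR** (VAF 0 in parental, > 0.1 in resistant), **VpPR** (positive in
both). Resistant-only variants at or below the 0.1 threshold remain
`unclassified` — the printed definitions leave that band open, and it is
reported rather than silently merged. "VAF of 0" is taken literally
from the caller output (a configurable `zero_epsilon` tolerates noisy
synthetic input).

A clonal variant on `c` of `p` tumour alleles at purity `f` has expected
VAF `f*c / (f*p + (1-f)*2)` (`expected_clonal_vaf()`); for a pure
near-tetraploid clone with a single-copy variant this is 0.25, the mode
that identifies clonal expansion. `vaf_density()` fits a Gaussian KDE on
[0, 1] (bandwidth: Silverman's rule clipped to [0.01, 0.1], since VAFs
live on a unit interval) and reports local maxima above 10% of the
global maximum, sorted by height. `per_chromosome_vaf()` repeats this
per chromosome to surface local copy-number shifts; chromosomes with
fewer than 10 variants are flagged low-support.

Bisulfite reads confound C>T (and G>A) changes, so validation of
variants in bisulfite data keeps only A>T / T>A substitutions covered
strictly above 15x (`wgbs_validation_filter()`).
`persistence_check()` then reports which VpRs remain present (VAF > 0)
and which VpPs remain absent in P12 — the test of whether the resistant
clone, not a surviving parental subpopulation, repopulated the culture.

## Dose-response and Loewe synergy

Single-agent viability follows the three-parameter log-logistic model
with Hill slope 1, `R(d) = bottom + (top - bottom)/(1 + d/IC50)`
("log(inhibitor) vs response, three parameters"); `fit_ic50()`
least-squares fits (IC50, top, bottom) with the IC50 on the log scale
and refuses degenerate fits (constant responses, IC50 outside 100x the
dose range). The Loewe-additive expected effect of a dose pair solves
`dA/A(E) + dB/B(E) = 1`; under shared plateaus this is closed-form,
otherwise it is solved by bisection over the jointly attainable
viability range (values outside it are clamped with a warning).
`synergy_matrix()` reports observed minus expected viability per grid
cell (negative = synergistic killing); single-agent margins are 0 by
definition of the reference model. A drug sham-combined with itself
yields zero synergy — the standard self-consistency check of any
Loewe implementation.

## The synthetic-data generator

Every module is exercised on synthetic data with planted ground truth
(`sim_config()` + `generate_*()`). Defaults encode the study
conditions: two cell lines and four states; planted DMRs of 4-30 CpGs
with a true shift of 0.4 of which 96% are hypermethylated and 10%
revert (P12 back at the parental level, P5 exactly halfway and hence
strictly between); per-CpG coverage Poisson(30); a near-tetraploid
(ploidy 4) clone sequenced at 40x with ~3000 resistant-only variants;
an IC50 of 12.70 nM (top 100, bottom 0) for the primary drug.

Choices the data do not dictate, made once and documented here:

* **Methylation noise** is beta-binomial with dispersion `rho = 0.02`
  (WGBS counts are overdispersed relative to binomial).
* **Background methylation** of non-DMR CpGs (not stated anywhere) is
  bimodal as in mammalian methylomes: Beta(8, 1.5) outside CpG islands
  (mostly methylated), Beta(1.5, 8) inside (mostly unmethylated).
* **Planted fractions are compositions**, not per-region coin flips:
  exactly `round(frac * n)` planted DMRs are hypermethylated/reverting,
  which keeps quantile-rule evaluations well-posed.
* **VAF noise** is binomial read sampling at fixed depth; purity is 1
  (cultured cells). Per-chromosome ploidy overrides model chromosome
  losses.
* **Viability noise** defaults to additive Gaussian (sd 2 viability
  points); replicate-recovery tests model a 5% coefficient of
  variation, as in luminescence readouts.
* Planted DMRs are non-overlapping with at least one non-DMR CpG
  between them, and the planted true level is constant within a DMR.

What the generator does *not* emulate: read-level data (no FASTQ, no
bisulfite-conversion errors), positional autocorrelation of methylation
beyond the planted regions, copy-number heterogeneity within a
chromosome, subclonal structure, and batch effects. Passing tests on
this generator therefore demonstrate correctness of the computations
under the stated noise models, not robustness to every artefact of real
sequencing data.

## Numerical conventions and problem sizes

All genomic coordinates are 0-based half-open; a shared endpoint is not
an overlap; conversion to 1-based happens only at the VCF boundary.
Threshold comparisons that the definitions state as inequalities are
implemented exactly as stated (strict `>` for the VpR 0.1 and the
15x coverage rules, `>=` for the 0.4 and 0.2 methylation differences,
strict `>` above the reverting quantile cutoff). The test and
acceptance workloads use desk-scale problem sizes chosen to keep the
full suite under a minute of simulation per scenario: 10 Mb genomes
with ~1e5 CpGs for DMR recovery, 2000-iteration enrichment runs
replicated 200 times for null calibration, 3000 variants for VAF
modes; each is a parameter, and study-scale values (e.g. 1e6
enrichment iterations) are reachable through the same interfaces.

## Known limitations

* The smoother is a documented stand-in, not a local-likelihood
  (BSmooth) reimplementation; with very sparse CpGs a CpG-count window
  can span large bp distances.
* The enrichment null conditions on the observed region set (paired
  replacement); it does not model uncertainty in the region calls
  themselves.
* Loewe expectations with differing plateaus are clamped at the edge of
  the jointly attainable range; strongly antagonistic surfaces near the
  plateaus are therefore conservative.
* `read_vcf()` handles the minimal AF:DP subset this pipeline writes,
  not the full VCF specification.
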