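---
title: "Methods: single-cell BCR repertoire analysis with bcrclone"
author: "bcrclone authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell BCR repertoire analysis with bcrclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrclone)
```

`bcrclone` analyses paired single-cell V(D)J data from multi-tissue B-cell
cohorts. This vignette is the package's methodological account: the models
and rules each stage implements, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, and the
numerical conventions and known limitations.

## Somatic hypermutation against germline

Each chain carries a gapped V-region alignment of the observed sequence and
its inferred germline. `count_mutations()` compares the two position by
position: a position is *comparable* when both symbols are unambiguous
bases (`A/C/G/T`); `N`, `.` and `-` in either sequence remove the position
from both the mutation count and the comparable length. The mutation unit
is therefore the nucleotide substitution; insertions and deletions are
never counted (gap columns are dropped). This is the conservative
convention when no indel rule is specified: indels in V(D)J data are rare
and frequently artefactual, and counting them would conflate alignment
quality with biology. An alignment with zero comparable positions is an
error, not a zero — a rate with an empty denominator is meaningless.

Distribution-style summaries (`shm_summary()`) use the mutation *rate*
`m / L`, which normalises for differences in effective read length; the
mutation threshold and the MBC-to-PC increment use integer *counts*,
because the threshold's semantics ("how many mutations can technical noise
produce?") are count-based.

## The naive-calibrated mutation threshold

Sorted naive B cells (IgD+CD27-) should carry germline-configured
receptors, so their apparent mutation counts estimate the noise floor of
the whole pipeline (sequencing error, imperfect germline assignment,
allelic variation). `calibrate_naive_threshold()` takes the nearest-rank
quantile of the naive count distribution: with `n` calibration counts
sorted ascending, the threshold is the value at rank `ceiling(q * n)`. A
chain is called mutated iff its count strictly exceeds the threshold, so at
most a `1 - q` fraction of naive-like chains can be mis-called, up to
sampling error — a guarantee that holds by construction, without any
distributional assumption.

Defaults: `quantile = 0.99`, minimum 50 calibration chains (an error below
that advises a fallback constant), heavy chains only
(`chain_scope = "heavy_only"`). The quantile-vs-(mean + k SD) choice and
the chain scope are exposed as configuration because upstream conventions
differ between studies; the quantile form was chosen as the default for its
distribution-free guarantee. Light chains are scored but do not enter the
MBC call, matching the heavy-chain (IgHV) emphasis of repertoire analyses.

## In-silico memory B-cell identification

Within the naive/memory compartment, `classify_mbc()` labels a cell MBC
iff its heavy chain is mutated (count above threshold) *or* class-switched
(IgG/IgA/IgE via the constant-gene call). Cells labelled GCBC or PC by
upstream transcriptome clustering pass through unchanged; IgD-expressing
unswitched cells below threshold remain naive-like. Cells without an
evaluable heavy chain are reported as unclassifiable and excluded from
MBC-level analyses rather than silently defaulted. An empty or unmatched
constant-gene call means "isotype unknown": such cells are excluded from
isotype-frequency denominators but retained for SHM summaries.

When a cell presents several heavy chains, `build_cell_table()` keeps the
chain with the highest `consensus_count`, falling back to the
lexicographically smallest `sequence_id`, and reports the affected cells —
a deterministic rule for a situation (doublets, ambient chains) whose
handling upstream tools rarely document.

## Clonotypes, expansion, diversity

`assign_clonotypes()` groups cells by donor, allele-stripped V gene,
allele-stripped J gene and the exact junction amino-acid sequence. Exact
junction identity is deterministic, conservative and standard for
single-cell data, where within-clone junction variation is limited; a
sensitivity-analysis option (`junction_nt_identity`) merges equal-length
junctions above a nucleotide-identity threshold by single linkage instead.
Clonotype identifiers are ordinals in sorted key order — no hashing — so
the assignment is invariant to input row order. Identical rearrangements in
different donors are distinct clonotypes: clonal descent is a within-donor
concept.

The expanded fraction of a compartment is the proportion of its cells whose
clonotype has two or more members *within that compartment*
(`expansion_scope = "donor_wide"` switches to donor-wide sizes). Diversity
is unnormalised Shannon entropy with natural logarithm. Because entropy
grows with sampling depth, cross-compartment comparisons should use
`rarefied_entropy()`: subsample a fixed depth (by default the smallest
compared compartment) without replacement, 100 resamples, and compare
means; the resampling is seeded and bit-reproducible.

## Clonotype sharing between subsets

`pairwise_similarity()` scores two clonotype identity sets of one donor
with the overlap coefficient `|A n B| / min(|A|, |B|)` — symmetric, in
[0, 1], equal to 1 under containment, and robust to the large size
asymmetry between memory and plasma-cell compartments. Jaccard is provided
for sensitivity analysis; clone-size weighting is deliberately absent so a
single hyperexpanded clone cannot dominate the readout. Compartments with
fewer than 10 clonotypes yield *missing* entries, not zeros: spurious zeros
from sparse compartments would otherwise drag group means down. Group-level
matrices are means of per-donor matrices — the donor is the unit of
replication, never pooled clonotypes. Cross-donor comparisons are an error.
An empirical null for observed similarities is available by permuting clone
labels within a donor (`similarity_permutation_null()`).

The MBC-PC sharing readout quantifies repertoire overlap only; the
directional interpretation (memory cells differentiating into plasma
cells) is a biological reading layered on top, and nothing in the package
claims to infer direction.

## Statistics

`compare_groups()` fronts the tests used in cohort figures: Welch
two-tailed t, paired t (pairs keyed by donor; unmatched donors are an
error), Mann-Whitney, and one-way fixed-effects ANOVA with Tukey HSD on
donor-level values. Zero-variance inputs with equal means return statistic
0 and p 1 rather than erroring, so degenerate simulated configurations
remain analysable. `correlate_with_disease()` reports Pearson r, the
two-sided p and the least-squares line; it requires at least three donors
and nonzero variance. `correlate_compartments()` maps the association over
many compartments and offers a Benjamini-Hochberg switch; raw per-panel
p values are the default, matching common practice for correlation dot
plots.

## Gene-signature scores

`score_signature()` implements expression-bin-matched control scoring:
genes are ranked by mean expression (ties broken by gene name, making the
score invariant to column order) and cut into `n_bins = 25`
equal-frequency bins; each gene-set gene draws `n_ctrl_per_gene = 100`
control genes from its own bin (excluding gene-set genes, with replacement
when the bin is small, widening to neighbouring bins only when a bin has no
eligible gene). The score is the mean gene-set expression minus the mean
control expression per cell, so under exchangeability of gene-set and
control labels its expectation is 0 — a property the tests exploit as a
null. Control sampling is seeded and reproducible. Shipped signature names
(S-phase, G2/M, light/dark zone, type I/II interferon response) are
placeholders emitted by the generator; real analyses should supply curated
GMT files.

## The synthetic cohort generator

`simulate_cohort()` realises a configurable multi-donor study:

- **Design.** Default `default_cd_scenario()`: 8 disease and 7 control
  donors; blood, colon and non-inflamed terminal-ileum samples for all
  donors, plus an inflamed terminal-ileum sample for disease donors; 150
  antigen-experienced cells per sample; 60 sorted naive blood cells for
  each of 5 donors for threshold calibration.
- **Clonal structure.** Within each donor and cell type, clone sizes follow
  a geometric law (success probability per cell type, default mean sizes
  1.05-2 cells) trimmed to partition the compartment exactly; clones span
  tissues, which is what makes cross-tissue sharing observable. Each clone
  receives a germline V (usage-weighted, with an optional disease-specific
  boost of one gene, default IGHV3-23 in disease MBCs) and an exact shared
  junction, so generator truth and the exact-junction clonotype rule
  coincide by construction.
- **SHM.** Per-cell mutation counts are Poisson with stratum means
  (cell type x disease group x region); substitutions are placed uniformly
  at distinct V positions, i.i.d., with no hotspot or replacement/silent
  structure — sufficient to exercise counting and thresholding, and a
  documented simplification. Defaults: naive 0.3; memory 6 (control) vs 4
  (disease); germinal-centre 8 vs 6; plasma cells 12 (control), 10
  (disease non-inflamed), 6 (disease inflamed) — making the designed
  MBC-to-PC increment 6 in non-inflamed and 2 in inflamed regions.
- **CSR.** Isotypes are drawn from stratum probability vectors; the
  disease-inflamed strata shift plasma cells from IgA toward IgG1 and
  memory cells toward IgM.
- **Sharing.** A fraction `s` of plasma cells (default 0.30 disease, 0.05
  control) is reassigned to clones containing memory cells of the same
  donor; `s = 1` forces the plasma-cell clonotype set inside the memory
  set and an overlap similarity of 1.
- **Severity scores.** Disease donors draw a resident-like MBC propensity
  from a Beta distribution (applied per tissue); the disease score is
  linear in the *realised* resident-like proportion among terminal-ileum
  MBCs plus Gaussian noise. When a target correlation is configured, the
  noise SD is calibrated against the realised cross-donor proportion
  spread (`sd_e = slope * sd(prop) * sqrt(1 / rho^2 - 1)`) so the model
  correlation equals the target. The canonical scenario targets 0.95: a
  pinned-seed regression over five simultaneous effects needs each effect
  detectable with near-certainty, and at 8 scored donors the two-sided
  critical |r| is 0.707, so a weaker design would fail by luck in a
  substantial fraction of runs even when implemented correctly. For
  calibration studies at donor scale, `simulate_donor_association()`
  provides the same proportion/score model directly (with the Beta's
  theoretical SD), which is how the type-I-error calibration (2000
  replicates) and correlation-recovery (200 replicates) studies are run at
  tractable cost.
- **Expression.** A small matrix (default 1000 cells x 300 genes,
  log-normalised units: per-gene Gaussian around log-normal-style
  baselines) with the type I/II interferon gene sets shifted upward
  (default +1 log-unit) in inflamed-region cells, plus matching GMT output,
  so signature tests never depend on curated biology.

Everything derives from one seed; identical configuration and seed
reproduce every output byte for byte. Ground truth (per-cell clone, cell
type, cluster, mutation count; per-donor propensities and scores; the
realised configuration) accompanies every cohort.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: V(D)J junction machinery (junctions are
random strings, not recombination products), SHM targeting and selection,
affinity maturation dynamics, doublets and ambient contamination,
batch/donor technical effects, realistic expression covariance (genes are
independent given their means), and dropout. Recovery tests validate the
*estimators* under a known model; they are not evidence about upstream
sequencing or alignment quality.

## Problem sizes and numerical conventions

The test suite runs the canonical scenario at roughly 8000 cells and 15
donors, and uses deliberately small designs elsewhere (3-4 donors, 60-80
cells per sample; 20 seeds for the sharing-monotonicity study, 50 for
expansion recovery, 2000 donor-level replicates for type-I calibration) —
sizes at which every designed effect is still comfortably detectable while
the whole suite runs in well under a minute. Ties in expression binning are
broken by gene name; clonotype ordinals follow sorted keys; all seeded
operations save and restore the caller's RNG state. Missing values in TSV
output are empty strings, never `"NA"`, for interoperability with non-R
AIRR tooling. Gene symbols match case-sensitively with no alias
resolution.

## Known limitations

Clonotyping is heavy-chain only (light chains are scored for SHM but do not
refine clones); convergent clonotypes across donors are out of scope;
lineage trees, hotspot-aware SHM models and replacement/silent
classification are not implemented; the expression layer is a minimal
substrate for signature scoring, not a realistic transcriptome simulator;
and expression normalisation is assumed done upstream (inputs are already
log-normalised).
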