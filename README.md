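# bcrclone

Single-cell B-cell receptor (BCR) repertoire analysis for multi-tissue
patient cohorts, built for studies of mucosal B-cell responses in chronic
intestinal inflammation (Crohn's disease-style designs: matched terminal
ileum, colon and blood samples from diseased and control donors).

Antigen-experienced B cells carry two sequence-level footprints of their
history: somatic hypermutation (SHM) of the immunoglobulin variable (IgV)
region and class-switch recombination (CSR) of the heavy-chain constant
gene. `bcrclone` turns paired single-cell V(D)J data into quantitative
readouts of both, and into clonotype-level measures of expansion, diversity
and inter-subset differentiation:

- **SHM quantification.** For each chain, mutations are counted as
  mismatches between the gapped V-region alignment and its germline
  (positions with `N`, `.` or `-` in either sequence are excluded from
  numerator and denominator), giving a per-chain mutation count *m*,
  comparable length *L* and rate *m/L*.
- **Naive-calibrated mutation threshold.** Flow-sorted naive B cells
  (IgD+CD27-) carry unmutated receptors, so their apparent mutation counts
  estimate technical noise. The threshold *t* is the nearest-rank quantile
  (default 0.99) of the naive count distribution; a chain is "mutated" iff
  *m* > *t*, which bounds the naive false-positive fraction by 1 - q.
- **In-silico memory B-cell (MBC) identification.** Within the naive/memory
  compartment a cell is an MBC iff its heavy chain is mutated and/or
  class-switched (IgG/IgA/IgE).
- **Clonotyping and expansion.** Cells sharing donor, allele-stripped V and
  J gene and the exact junction (CDR3) amino-acid sequence form a
  clonotype. The expanded fraction of a compartment is the proportion of
  its cells in clonotypes of size >= 2; diversity is Shannon entropy
  H = -sum p_i log p_i, with depth-matched rarefaction for fair cross-group
  comparison.
- **Clonotype sharing between subsets.** For two compartments A and B of
  one donor, similarity is the overlap coefficient |A n B| / min(|A|, |B|)
  (Jaccard optional). Elevated MBC-PC sharing is the repertoire-level
  readout of direct MBC-to-plasma-cell differentiation.
- **Signature scoring and association.** Per-cell gene-signature scores use
  expression-bin-matched control genes; donor-level subset proportions are
  tested against disease-severity scores (SES-CD-like) by Pearson
  correlation with least-squares regression lines.

A fully seeded synthetic cohort generator (`simulate_cohort()`) emulates
the study design — multi-donor disease/control groups, four sample types,
clonal lineages with Poisson SHM, stratum-specific isotype vectors, a
tunable MBC-PC sharing fraction, V-gene usage skew, interferon-signature
expression shifts and severity scores tied to resident-like MBC
proportions — and returns complete ground truth, so every pipeline stage
has a parameter-recovery test.

## Worked example

```r
library(bcrclone)

cohort   <- simulate_cohort(default_cd_scenario(seed = 1))
analysis <- analyze_repertoire(cohort$airr, cohort$metadata, cohort$donors)
analysis
summary(analysis)
```

```
BCR repertoire analysis
  cells analysed: 7950 in 15 donors; 4611 clonotypes
  mutation threshold: 2 (quantile 0.99 on 300 naive chains)
  cell types: GCBC=820, MBC=3147, NBC=993, PC=2990
Cohort-level disease contrasts
  SHM rate, CD vs nonIBD:                    CD=0.02218 vs nonIBD=0.02966, p = 6.14e-115
  IgA PC freq, inflamed vs non-inflamed TI:  inflamed=0.4715 vs non_inflamed=0.7327, p = 7.83e-05
  IgG1 PC freq, inflamed vs non-inflamed TI: inflamed=0.3499 vs non_inflamed=0.1185, p = 0.000104
  IgM MBC freq, inflamed vs non-inflamed TI: inflamed=0.4015 vs non_inflamed=0.2192, p = 0.000136
  MBC-PC similarity, CD vs nonIBD:           CD=0.2226 vs nonIBD=0.03423, p = 6.53e-06
  resident-like MBC prop vs disease score:   r = +0.898, p = 0.00247 (n = 8)
```

Reading the output: the canonical synthetic scenario designs five disease
effects (impaired SHM in disease, an IgA-to-IgG1 switch shift in inflamed
plasma cells, an IgM rise in inflamed memory B cells, elevated MBC-PC
clonotype sharing, and a positive association between resident-like MBC
proportion and disease severity), and the pipeline recovers each: the mean
mutation rate is lower in the disease group, the paired isotype contrasts
move in the designed directions, clonotype sharing between memory and
plasma cells is roughly six-fold higher in the disease group, and the
donor-level proportion-severity correlation is strongly positive.

Real data enter through the same interfaces: `read_airr()` (AIRR
Rearrangement TSV), `read_cell_metadata()`, `read_germline_fasta()`,
`read_gene_sets()` (GMT) and `read_expression()` (dense TSV or
MatrixMarket).

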