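---
title: "Pooled CRISPR knockout screen scoring and companion quantifications"
author: "screenforge developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled CRISPR knockout screen scoring and companion quantifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenforge)
```

## The analysis problem

A genome-wide pooled knockout screen for differentiation regulators
infects a cell population with a Brunello-like sgRNA library (4 guides
per gene), treats one arm with a differentiation inducer, sorts the
marker-positive (differentiated) fraction, and sequences the integrated
guide cassettes of both arms.  Genes whose knockout promotes
differentiation show their guides enriched in the sorted arm.
`screenforge` implements the full quantitative path from raw reads to
ranked genes, plus the small downstream quantifications such studies
lean on (relative expression by qPCR, ChIP enrichment, protein
half-life from a cycloheximide chase, differential-expression filtering
and gene-set overlap).

## Read model and extraction

Each sequencing read contains, 5' to 3': an optional 8-nt sample
barcode, a short stagger of variable length (a base-diversity device),
the vector sequence ending in the invariant anchor `CACCG`, the 20-nt
spacer, and the scaffold.  Extraction searches each read for the
*leftmost* exact occurrence of the anchor and takes the next 20 nt as
the spacer.  The leftmost rule is deliberate: the vector's anchor copy
precedes the insert, so an anchor recurring downstream by chance never
shadows it.  Every read receives exactly one status, in the fixed
precedence order `unknown_barcode` → `no_anchor` →
`insufficient_length` → `unmapped_spacer` → `ok`, and failing reads are
tallied, never dropped, so status counts always sum to the number of
reads processed.

Spacer-to-library matching is exact by default.  With
`max_mismatch = 1` a read is rescued only when exactly one library
spacer sits at Hamming distance 1; ties stay unmapped.  Quality scores
are ignored: the construct is fixed-sequence, and the anchor plus exact
20-mer match is itself a stringent filter.

Barcodes live physically in the index primer, so the raw-file layout
varies between sequencing providers.  Two demultiplexing modes are
provided: `per_file` (one FASTQ per sample, the common deliverable) and
`inline_prefix` (barcode as the first 8 read characters, which the
simulator can emit to exercise the demultiplexer).  Matching is exact;
an 8-nt barcode set at pairwise distance ≥ 2 makes single errors fail
loudly rather than mis-assign.

## Normalization and scoring

Counts are normalized per sequenced sample to reads per million
(`count / column total × 10^6`) and then log2-transformed after adding
a pseudocount of 1, which keeps zero-count guides finite (`log2(1) =
0`).  Each barcoded sample is one condition of the plate layout, so
"per condition" normalization is per column; replicate averaging, when
replicates exist, happens at the scoring stage on the log scale.

The **guide score** is the median-corrected log2 fold change: for
guide *g*,

    lfc_raw(g)      = mean(log2 treated) − mean(log2 control)
    lfc_corrected(g) = lfc_raw(g) − median over all guides of lfc_raw

Global median centering removes the compositional shift that
closed-sum (multinomial) sequencing imposes: since most guides do
nothing, the median guide is an estimate of "no effect".  Correction is
idempotent and invariant to adding a constant to either arm.

The **gene score** is the mean of the gene's guides' corrected scores.
A gene is called a hit when at least `min_concordant` (default 3) of
its guides shift in the same direction by more than `tau` log2 units.

### Why tau defaults to 0.5, not 0

A pure sign rule (`tau = 0`) cannot work: under the null, a guide's
corrected log fold change is symmetrically distributed around zero and
essentially never exactly zero, so its sign is a fair coin.  The chance
that ≥ 3 of 4 independent coins agree in some direction is 10/16 =
62.5%, *independent of sequencing depth* — a sign-only concordance rule
calls most untouched genes.  The package therefore requires a
*meaningful* per-guide shift, defaulting to `tau = 0.5` log2 units
(≈ 1.4-fold).  At a typical per-guide depth of a few hundred reads the
null standard deviation of a corrected LFC is on the order of 0.05–0.1
log2 units, so 0.5 sits many null standard deviations out (empirical
null false-hit rate ≈ 0 in the test suite) while a true 4-fold
(`effect_log2 = 2`) enrichment clears it with a wide margin.  `tau`
remains a plain parameter for users who want the raw sign rule.

`min_concordant = 3` follows the "at least three of four" reading; a
stricter 4-of-4 variant is one argument away.  Genes with fewer guides
than `min_concordant` are flagged not-callable rather than silently
skipped.  No p-value or FDR is attached: the selection rule *is* the
concordance criterion, and the package does not dress it up as a test.

Ranking places hits of the requested direction first, by absolute gene
score, with lexicographic tie-breaks for determinism.

## Companion quantifications

* **qPCR.** Relative expression is `2^−ΔΔCt` with amplification
  efficiency fixed at 2: ΔCt subtracts the reference gene (e.g.
  β-actin), ΔΔCt subtracts the control sample, so the control's fold
  change is 1 by construction and a global cycler offset cancels.  The
  s.e.m. of ΔΔCt is propagated by quadrature of the four component
  s.e.m.s and reported, never used for gating.
* **ChIP.** Enrichment is ΔCt = mean Ct(IP) − mean Ct(input), reported
  on the `2^−ΔCt` fold-of-input scale (the display scale is a package
  choice; the ΔCt normalization is the substance).
* **Half-life.** Cycloheximide-chase band intensities are fitted by
  ordinary least squares of `ln(intensity)` on time; `k = −slope`,
  half-life `= ln 2 / k`, with `r²` reported.  First-order (log-linear)
  decay is the standard reading of a chase experiment; plateau and
  two-phase models are out of scope.  Non-decaying fits (`k ≤ 0`)
  return an infinite half-life with a flag rather than a negative
  number.  Zero intensities are rejected unless an explicit floor
  (`epsilon`) is supplied.
* **DEG filter and overlap.** Up: `FC ≥ 1.5` and `p < 0.01`; down:
  `FC ≤ 1/1.5` and `p < 0.01`.  The fold boundary is inclusive (the
  source conventions disagree between "at least 1.5-fold" and
  "> 1.5"; the inclusive reading is fixed here and configurable).  When
  replicates are supplied instead of p-values, a two-sided Welch t test
  is computed as documented plumbing.  Set overlap reports
  `100 × |A∩B| / |A|` and, as an optional annotation, the upper-tail
  hypergeometric probability of the observed-or-greater overlap.

## What the simulator emulates — and what it does not

`simulate_screen` draws baseline guide abundances log-normal(0, σ²)
(default σ = 1, matching the order-of-magnitude coverage inequality of
real pooled libraries), multiplies every guide of an enriched gene by
`2^effect_log2` (default 2, a strong sorting-based enrichment) in the
treated arm, and draws per-sample counts multinomial at fixed depth
(default 10^6 reads per arm, desk-scale for a 4,000-guide library).
Reads are emitted with a random 0–7 nt stagger, the vector tail ending
in `CACCG`, the spacer, and a scaffold suffix, with optional per-base
substitution noise.  Defaults mirror the stated screen design: 4 guides
per gene, two arms, one sample each.

Deliberate simplifications: multinomial rather than negative-binomial
counts (no overdispersion estimate exists to calibrate one; abundance
inequality comes from the log-normal baseline instead); no PCR
jackpotting, no infection-MOI dynamics, no sorting impurity; staggers
are rejection-sampled so they never create a spurious upstream anchor,
because real stagger primers are fixed sequences designed not to clash
with the vector — without this the zero-noise identity between emitted
reads and truth counts would be unattainable under the leftmost-anchor
rule.  A green recovery test therefore establishes correctness of the
arithmetic pipeline under the stated generative model, not robustness
to overdispersion, chimeric PCR, or index hopping.

`simulate_qpcr` inverts the ΔΔCt arithmetic exactly (control target Ct
25, reference Ct 20, treated target Ct `25 − log2(fold)`) with
Gaussian replicate noise; `simulate_decay` is exact first-order decay
with mean-1 multiplicative log-normal noise of a given coefficient of
variation.  All generators are fully deterministic under a seed and
leave the caller's RNG state untouched.

## Numerical and degenerate-input conventions

* RPM columns of positive total sum to 10^6 within 10^-6 relative
  tolerance; all-zero samples are an error unless explicitly allowed.
* Median centering is exact to floating tolerance; ties at `tau` are
  neutral (strict inequalities), making the boundary testable.
* TSV output rounds to 4 decimals; exactness claims apply to in-memory
  values.
* Library loading uppercases spacers and rejects non-ACGT characters,
  duplicate guide ids and duplicate spacers, naming the offending rows.

## Limitations

The scoring path covers the concordance-rule family of screen
analyses; it intentionally implements no RRA/MLE screen statistics, no
copy-number or essentiality correction, and no control-guide
normalization (the stated library design has no special control-guide
class).  Microarray preprocessing, ontology annotation and image
densitometry are out of scope: the expression and decay modules consume
already-quantified tables.
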