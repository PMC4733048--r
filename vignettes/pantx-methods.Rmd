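---
title: "Methods: presence/absence variation analysis with pantx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence/absence variation analysis with pantx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pantx)
```

`pantx` analyses pan-transcriptomes of diverse inbred panels: which
genes are expressed in which lines, which of the off/on patterns trace
back to physical deletions, what they do to traits and hybrids, and how
large the union of expressed genes becomes as lines are added.  This
vignette documents the statistical methods, the modelling assumptions,
and the defaults of the synthetic-panel generator used to validate them.

## ePAV calling

A gene is scored by the number of lines expressing it (value > 0).
With `n` lines and a minimum presence fraction of 5%, the gates are
`L = ceiling(0.05 n)` and `U = n − L − 1`: fewer than `L` expressing
lines means the gene is too rare to call (indistinguishable from
artefacts), more than `U` means core, the rest are ePAV candidates.  At
`n = 368` this yields the (19, 348) pair; at `n = 38` the lower gate is
2.

```{r gates}
presence_gates(368)
presence_gates(38)
```

Each candidate is then ternary-encoded per line by `binarize_gene()`.
The nonzero values are histogrammed into 10 equal-width bins spanning
their range.  A nonzero value is masked to `NA` when it falls in bin 1
(the lowest expression decile of the range, where presence is
ambiguous) or in any bin occupied by fewer than 3 values (isolated
outliers); remaining nonzero values become 1 and zeros become 0.  Both
masking rules are evaluated against the single initial histogram, and a
gene whose nonzero values are all equal is left untrimmed.  After
masking, the presence fraction among non-`NA` states is re-checked
against `[0.05, 0.95]`; genes pushed outside the band are dropped.  The
histogram width is a function of the value range only, so the encoding
is invariant under positive rescaling of a gene's expression.

```{r binarize}
v <- c(0.1, seq(2.1, 2.45, by = 0.05), 9.9, 0, 0)
binarize_gene(v)
```

## Genomic PAV prediction and concordance

On a SNP array, a deleted segment produces a run of missing calls.  A
line is a *potential PAV* for a gene when every marker in the gene body
± 1 kb is a missing call in that line; genes with fewer than 2 window
markers are not assessed.  A gene is a *candidate PAV* when potential
PAV occurs in at least `ceiling(0.05 n)` lines — 19 at `n = 368` for a
sparse array, 2 at `n = 38` for a dense one.  `concordance()` compares
expression-level and genomic-level calls cellwise (ignoring cells `NA`
in either) and splits the inconsistencies into "genome present but not
expressed" (expected: presence of the sequence does not force
expression) and "expressed without genomic support" (unexpected;
array artefacts).

## Presence/absence GWAS

Each (gene, trait) pair is tested by ordinary least squares of the
trait on `[intercept, state, PCs]`, where the state is the ternary ePAV
code (`NA` lines are dropped per test) and the PCs are principal
components of the mean-imputed, centred genotype matrix.  The p-value is
the two-sided t-test of the state coefficient.  Markers with fewer than
5 lines in either state class are skipped with a recorded reason.  The
scan-wide threshold is `1/n_markers` — `1/2355 = 4.25E-4` for a scan of
2,355 markers.  This is a deliberately permissive screening threshold;
downstream interpretation should treat hits as candidates.

## Composite LD placement of novel sequences

Sequences absent from the reference cannot be positioned directly, but
their SNPs can be correlated with positioned reference SNPs.  With
unphased dosages, haplotype-level LD is not identifiable; `pantx` uses
*composite* LD, the squared Pearson correlation of dosage vectors over
pairwise-complete entries (at least 10, both vectors polymorphic).  A
novel sequence is placed at the reference gene containing the
best-correlated reference SNP — falling back to the nearest gene on
that chromosome — provided the best r² exceeds 0.1; exact ties break
deterministically by (chromosome, position).

## Pan-transcriptome size

`rarefy()` draws, per repetition, a random permutation of lines and
scores its prefixes of size 20, 40, … ("adding 20 lines at a time",
samples nested within a repetition, 10 repetitions by default).  Within
a subsample, the pan count is the number of genes present in at least
one line, the core count the number present in more than
`floor(0.95 n)` lines, and the dispensable count their difference.
`fit_asymptote()` fits the increasing component with the exponential
saturation curve `y(n) = A − B·exp(−n/C)` by multi-start
Levenberg–Marquardt with the constraint `A ≥ max(y)`, so the estimated
asymptote never undershoots the data.  A Heaps-law power curve
(`model = "power"`) is available to diagnose non-saturating (open)
pan-transcriptomes.  `pan_summary()` composes core + dispensable +
novel components (counts or fits) into a total with nearest-thousand
rounding.

One boundary note: because the core rule compares against
`floor(0.95 n)`, the mean core curve is not mathematically guaranteed
to be non-increasing in `n` at points where `floor(0.95 n)` steps (a
gene present in 19 of 20 sampled lines is not core, one present in 39
of 40 is).  In practice the curve decreases; the property suite tests
monotonicity only where it provably holds.

## Heterosis and complementation

For each hybrid, mid-parent heterosis is `F1 − (P1 + P2)/2`, reported
relative (percent of the mid-parent value, `NA` when the mid-parent is
0) by default.  The predictor is the number of *complementary* genes —
present in exactly one parent — over a chosen gene set (called ePAVs,
novel genes, or any ternary matrix); genes `NA` in either parent are
excluded from the count.  `heterosis_correlation()` reports, per trait,
the Pearson r², the regression slope, quantile-binned means of
heterosis against the count, and a permutation p-value obtained by
shuffling heterosis values across hybrids.  Complementary counts are
cached per parent pair, since they do not depend on the trait.

## The synthetic panel generator

`simulate_panel()` provides ground truth for every pipeline stage.  All
randomness flows from a single seeded stream with a fixed draw order, so
a seed pins every output byte.

* **Panel**: 300 lines in 3 subpopulations.
* **Genotypes**: 4,000 SNPs on 5 chromosomes; two latent AR(1) Gaussian
  haplotypes per line (`ld_decay = 0.8` between adjacent markers)
  thresholded at subpopulation-specific allele frequencies
  (base frequency ± N(0, 0.15), clamped to [0.05, 0.95]); 2% background
  missing calls.
* **Genes**: 300 core genes (expressed everywhere, with a dropout cap
  keeping them above the 95% presence gate), 200 ePAV genes, 30 novel
  sequences.  Expression is lognormal per gene with 2% dropout and a
  rare (5 × 10⁻⁴ per cell) 10–50× inflation emulating quantification
  artifacts; an absent gene has expression exactly 0.
* **ePAV mechanism**: 99% of ePAV genes are switched by a *trans*
  regulator SNP on a different chromosome (carrier dosage ≥ 1 means
  "on", with a 2% flip error).  Regulator SNPs are sampled without
  replacement at a minimum index gap of 8 on a chromosome, so distinct
  genes map to distinct loci rather than one shared haplotype.  The
  remaining ~1% (`frac_epav_genomic = 0.01`) are genomic PAVs: the gene
  is deleted in a subpopulation-biased set of lines, its expression is 0
  there, and all array markers in the gene window are set to missing —
  exactly the signature `predict_pav()` looks for.
* **Novel sequences**: each is anchored at a reference SNP inside a gene
  body; its 1–5 SNPs copy the anchor dosage with 3% per-line
  resampling, keeping anchor–novel r² around 0.9.  The truth target for
  placement is the gene containing the anchor.
* **Traits**: six yield-like traits, each the sum of a baseline (20), a
  subpopulation shift (SD 0.3), unit effects of 3 causal ePAV genes,
  and N(0, 0.5) noise.  Causal genes are drawn from trans-ePAV genes
  with truth presence in [0.25, 0.80], no inflated outlier cell, and
  less than 30% of state variance between subpopulations — a state
  collinear with structure is absorbed by the PC correction and carries
  no recoverable signal, and a state near the calling band can be
  dropped by the MAF re-check.
* **Hybrids**: the last line is the tester; the first 100 lines are
  crossed to it.  `F1 = mid-parent + 0.2 × (complementary non-core
  genes) + noise`.  With ~85 complementary genes per cross this yields
  mid-parent heterosis around 85% of the mid-parent value, typical of
  yield components, and keeps the planted slope detectable above the
  noise that NA masking adds to measured complementary counts.

### Validation

The acceptance suite (`tests/testthat/test-acceptance.R`) checks, at
the default configuration and a fixed seed: ≥ 90% recovery of planted
ePAV labels with ≤ 5% core mislabels; ≥ 90% recovery of planted genomic
PAV candidates with zero unplanted candidates; every planted GWAS
effect significant with false positives within a Poisson 99.9% bound at
the `1/n` threshold; ≥ 90% correct LD placements; a pan asymptote
within 10% of the closed truth; a positive, permutation-significant
heterosis slope for every trait; the ~1% genomic share of called ePAVs
(binomial CI covering 0.01); and a marker-test type-I error within
[0.03, 0.07] at nominal 0.05.  These thresholds were verified across
twelve seeds before being frozen; `scripts/acceptance.R` recomputes the
underlying metrics for any seed.

## Limitations

The generator is a caricature of real panel data: it has no read-depth
model (ePAV calls on real RNA-seq depend on library size), no linkage
between regulator and gene beyond chromosome assignment, a single
tester rather than a factorial crossing design, and independent
lognormal expression rather than correlated co-expression modules.  It
is designed to exercise every code path and identifiability boundary of
the pipeline, not to emulate any particular dataset.
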