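---
title: "Models and methods behind balproteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind balproteo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balproteo)
```

## Scope

`balproteo` implements a label-free quantitative proteomics analysis of
acellular bronchoalveolar lavage (BAL) fluid for lung-cancer cohorts:
preprocessing of per-search-engine quantitative matrices, moderated
two-group differential expression, a cross-engine consensus biomarker list,
PCA-based patient stratification with a separation-probability statistic,
replicate and saturation quality control, hypergeometric functional
enrichment, and gene-level multi-study consensus aggregation. Because raw
clinical LC-MS data of this kind are rarely depositable, the package ships
a first-class synthetic cohort generator with known ground truth; every
downstream stage is exercised and tested against planted effects.

## The synthetic cohort model

`cohort_design()` fixes the generative model. Its defaults emulate a
90-patient observational cohort of suspected lung cancer undergoing
diagnostic bronchoscopy, followed for two years: 49 cancer cases, 39
non-cancer controls and 2 still-suspicious patients at follow up, of whom
13 "converters" were labeled non-cancer at sample collection but diagnosed
with cancer during follow up. Samples are prepared in 5 batches, and 34
samples are re-run as technical replicates, giving 90 + 34 = 124 LC-MS
runs.

The quantitative model, all on the log2 scale:

* Baseline protein abundance: `b_p ~ N(20, 3)` (log-normal on the linear
  scale), covering the ~5 orders of magnitude typical of iBAQ estimates.
  Proteins specific to extracellular space (+3) and extracellular
  vesicular exosomes (+2) are shifted upward, reproducing the dominance of
  secreted and vesicular proteins in BAL fluid; nuclear proteins are
  shifted slightly down (−0.5).
* Planted regulation: a configurable number of proteins (default 120 of
  1200) receive a log2 effect drawn uniformly from [1.5, 3.5] with random
  sign, added to every sample carrying the cancer proteome signal. Cases
  *and* converters carry the signal — the converters' proteome already
  reflects their later diagnosis, which is what makes the stratification
  analysis informative.
* Nuisance variation: per-(protein, batch) offsets with sd 0.3, and
  per-(protein, sample) biological noise with sd 1.
* Detection (the data-dependent-acquisition dropout): a value with latent
  log2 abundance `y` is detected with probability
  `plogis((y − 14) / 2)`; undetected values are stored as 0, matching the
  `log2(x + 1)` convention downstream. With the default baseline this
  yields roughly 10–15% missingness concentrated in low-abundance
  proteins, emulating match-between-runs-assisted quantification.
* Engines: two search engines observe the same latent values through
  independent `N(0, 0.5)` measurement noise and independent detection
  draws; engine B additionally drops each protein entirely with
  probability 0.02, emulating search-engine disagreement.
* Quantitation types: protein and peptide LFQ are the exponentiated latent
  values; iBAQ divides by a per-protein theoretical peptide count
  (uniform 5–35); spectral counts are Poisson with rate
  `20 · 2^(y − 20)` (expected count 20 at baseline mean abundance).
  Peptide-level rows split each protein's intensity by fixed
  Dirichlet-like weights.
* Technical replicates re-observe the same biological aliquot (the
  biological noise draw is shared) in a different batch, with smaller
  measurement noise (sd 0.25) and fresh detection draws.

Identical design and seed give bit-identical datasets. What the generator
does **not** emulate: peptide sequences and their physicochemical detection
biases, retention-time structure, correlated (co-regulated) protein
modules, interfering identifications, and overdispersed counts (counts are
pure Poisson; overdispersion is left as a configuration hook). Passing
tests therefore demonstrate correctness of the analysis machinery under a
plausible missing-not-at-random generative model, not performance on real
LC-MS data.

## Preprocessing

Raw matrices are preprocessed in the fixed order: contaminant removal →
`log2(x + 1)` → quantile normalization → Gaussian abundance filtering,
yielding variants `log`, `log+qn`, `log+qn+filter`. Two engines × five
quantitation types × three variants = 30 matrices (six per quantitation
type).

Numerical choices:

* Quantile normalization maps each column to the entry-wise mean of the
  per-column sorted vectors by within-column rank; tied values receive the
  mean of the reference values over their tie-group's rank range. Zeros
  participate like any other value. The operation is idempotent (exactly,
  for tie-free columns).
* The abundance filter chooses a row-mean threshold from the deterministic
  candidate grid of the 0%, 5%, …, 50% quantiles of row-mean abundance,
  scoring each candidate by the Anderson–Darling statistic of the pooled
  nonzero retained values **divided by the pool size**. The raw statistic
  grows linearly with n at fixed distributional discrepancy and would
  mechanically favor the heaviest filtering; `A²/n` estimates the
  size-invariant discrepancy, so an already-Gaussian pool selects the
  smallest threshold and a zero-inflated low mode moves the threshold
  between the modes. Ties break toward the least filtering. The full
  (threshold, score) trace is returned for audit.

## Moderated differential expression

The lung-cancer vs non-lung-cancer contrast uses the collection-time
diagnosis labels with suspicious samples excluded, so converters sit in
the control group — as they would in a prospective analysis. Per protein,
the log2 fold is the difference of group means and the residual variance
the pooled within-group variance with `n₁ + n₂ − 2` degrees of freedom.

The empirical-Bayes moderation is implemented in the package (not
delegated): under the scaled-F sampling model `s²_g ~ s₀² F(d_g, d₀)`, the
prior `(d₀, s₀²)` is estimated by method of moments on
`log s²_g` with digamma/trigamma bias corrections (the trigamma inverse is
solved by Newton iteration); when the observed spread of the corrected
log-variances does not exceed what the residual degrees of freedom imply,
`d₀ = ∞` (complete shrinkage). The posterior variance
`s̃²_g = (d₀ s₀² + d_g s²_g)/(d₀ + d_g)` yields the moderated t with
`d₀ + d_g` degrees of freedom; `d₀ = 0` recovers the ordinary pooled t.
Benjamini–Hochberg step-up adjustment is applied across all tested
proteins. Proteins undetected in every used sample are dropped before
fitting. The implementation is cross-checked in the test suite against an
independent reference implementation of variance shrinkage.

## Cross-engine consensus

A protein enters the consensus list iff (1) its adjusted p is below 0.05
in **both** engines, (2) it is more than two-fold regulated
(`|log2 fold| > 1`, strict) in at least one engine, and (3) both engines
agree on the direction. The both-engine reading of rule 1 was chosen
because rule 3 already presumes both engines report the protein and the
construction exists to reduce software bias. Fold changes are computed on
the preprocessed (log-transformed, normalized) values.

Which preprocessing variant feeds the contrast was genuinely open. The
package defaults to `log+qn`: the abundance filter optimizes the pooled
value distribution, which is valuable for ordination, but it removes
low-abundance proteins wholesale and therefore biases a biomarker search
against genuinely regulated low-abundance proteins — on planted-effect
simulations it roughly halves recall. The filtered variant remains the
default input to the PCA stratification. Both are configurable.

Proteins detected only in cancer samples (and in no control or suspicious
sample) are reported separately by `cancer_exclusive_proteins()`; such
proteins are mostly identified in few samples and would not reach
significance, but are candidate subtype markers.

## Stratification and the separation probability

PCA uses the abundant proteins (detected in at least 50% of samples — the
cutoff is a configurable definition, chosen over a magic count threshold),
protein-wise mean centering without variance scaling (spectral counts
share a scale), and SVD. Component signs are fixed so the case-group mean
PC1 score is at least the control-group mean.

The separation probability asks whether converter placement on PC1 could
be chance: if `n/N` collection-time non-cancer samples separate from the
cancer cluster, the chance that none of `k` converters lands on the
separated side is `(1 − q)^k` with `q = round(n/N, 2)`. The rounding of
`q` to two decimals before exponentiation is deliberate, reproducing the
published arithmetic of the emulated cohort (`18/54 → 0.33`,
`(1 − 0.33)^13 = 0.005`); the unrounded value is also reported.

Replicate QC reports the mean Euclidean distance over all sample pairs
and over technical replicate pairs (replicates of the emulated cohort sit
markedly closer than unrelated samples), with a complete-linkage tree
(columns pre-sorted by sample id for deterministic ties). Identification
overlap between runs uses the Jaccard index (a both-empty pair is defined
as 1), and saturation curves accumulate the union of identifications over
runs, with a permutation band; the terminal value is order-invariant.

The baseline-characteristics table is summarized per category level with
the one-degree-of-freedom equal-proportions goodness-of-fit chi-square on
the (non-cancer, cancer) counts — the only reading consistent with all
printed raw p-values of the emulated cohort's table — with BH adjustment
across tested levels; levels coded unknown are counted but not tested.

## Functional enrichment

Per-sample enrichment uses the upper-tail hypergeometric probability
`P(X ≥ k)` against a background of all genes identified across the
dataset (not the genome — the contrast of interest is between samples,
which share the instrument's detectable universe). Identification (any
nonzero value) defines a sample's gene set. Categories significant in at
least one sample (adjusted p < 0.05) are retained and their per-sample
counts compared between groups by a chi-square on the 2×2 summed
in-category/out-of-category table and a two-sided Mann–Whitney U-test
(exact for groups of ≤ 10 without ties, normal approximation with tie
correction otherwise), each family BH-adjusted. The 2×2 construction is an
interpretation: the emulated analysis left its chi-square under-specified.
Category-level abundance comparisons (e.g. total exosome spectral counts,
total CD-molecule iBAQ) sum member rows per sample and apply the same rank
test. Compartment summaries assign a gene to one of the five major
cellular components only if annotated to exactly that one (specificity
rule), report mean `log2(x + 1)` per compartment, and emit the Venn
partition counts.

## Cross-study consensus

Protein-level calls are collapsed to encoding genes (isoform conflicts
exclude the gene — conservative, since the alternative silently picks a
winner). A gene is a multi-study consensus biomarker iff at least three
studies report it with the identical dominant direction; an exact
up/down tie is ambiguous and excluded. Any three concordant studies
qualify — membership does not require this study's own list, matching the
"three or more experiments" reading. Non-significant and not-detected are
merged into one code. The gene × study matrix is coded −1/0/+1 and studies
are clustered by Hamming distance with complete linkage, which reproduces
the tissue-versus-fluid grouping qualitatively. COPD comparison tables
flag direction-concordant genes as potential chronic-disease confounders.

## Problem sizes and determinism

All randomness flows from explicit integer seeds; `generate_cohort()` is
bit-reproducible and `run_pipeline()` writes a manifest whose output MD5
hashes are identical across reruns of the same configuration and seed.
The test suite validates the stochastic properties at these sizes, chosen
to make the Monte-Carlo error small relative to the tested margins:
type-I control on 100 null cohorts of 30 samples × 200 proteins;
planted-effect recovery on 20 cohorts of 80 samples × 1000 proteins with
100 planted effects (recall ≥ 0.7, false-discovery proportion ≤ 0.10);
converter placement on 20 full 124-run cohorts; hypergeometric p-values
against exhaustive enumeration for all backgrounds up to size 12; BH
against a brute-force step-up on 1000 random vectors; prior-df recovery
within 25% on 5000 simulated variances.

## Known limitations

* The noise laws (log-normal abundance, logistic detection, Poisson
  counts) are stand-ins: the emulated study does not state its
  quantitation's noise law, so these are configuration, not claims about
  real BAL data.
* The moderated model fits the two-group contrast only; batch enters the
  simulation but not the design matrix (matching the emulated analysis).
  Covariate adjustment is out of scope.
* Peptide-to-protein rollup and missing-value imputation are deliberately
  absent; zeros are carried through `log2(x + 1)`.
* The published consensus list itself (133 proteins) is not reproducible
  without the underlying raw data; the package validates the construction
  on planted truth instead.
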