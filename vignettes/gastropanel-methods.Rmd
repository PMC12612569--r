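---
title: "Methods: panel-based gastric cancer subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-based gastric cancer subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastropanel)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which tunable parameters
matter, what the synthetic-data generator does and does not emulate, and
where the numerical conventions were genuinely open.

## The measurement model

A targeted panel run measures raw molecular counts for ~107 endogenous
genes per sample, plus positive-control probes on a known spike ladder
(128 down to 0.125 fM) and negative-control probes measuring background.
Samples are processed on cartridges, and cartridge is the dominant
unwanted factor: the same RNA run on two cartridges can differ by a full
log2 unit. The working scale throughout is `log2(count + 1)`; the
pseudocount of 1 is a convention chosen so that zero counts map to zero
log-expression (the instrument reports integer counts and the exact
pseudocount is immaterial at panel-typical expression levels of
2^5–2^10).

### Sample QC

QC gates follow the instrument's documented defaults, exposed via
`qc_thresholds()`:

* imaging: fraction of fields of view counted ≥ 0.75;
* binding density within [0.1, 2.25];
* positive-control linearity: R² of log2 counts against log2 spike
  concentration ≥ 0.95 (a sample with constant positive-control counts
  fails, since no linear signal is present);
* limit of detection: LOD = mean + 2 sd of the negative probes; a sample
  fails when the 0.5 fM positive probe or the mean endogenous count
  falls below its LOD.

These are conventions, not a reproduction of any specific run's flags;
they are therefore all overridable. Missing imaging metadata leaves the
corresponding flag passing rather than excluding the sample. Gating is
idempotent by construction.

## RUV-III and negative-control selection

RUV-III removes unwanted variation using technical replicates encoded in
a membership matrix `M` (samples × biological units, row sums one) and a
set `c` of negative-control genes. The implementation is the literal
six-step estimator (residualize replicates, SVD, loadings, control
restriction, factor estimate, subtraction) described in
`?ruv3_normalize`; no additional centering is applied beyond the
replicate residualization. Two practical notes:

* If all samples are identical replicates of one unit, the residual
  matrix is exactly zero and the data are returned unchanged rather than
  attempting an SVD of a null matrix.
* A numerically singular control Gram matrix (`α_c α_cᵀ`) aborts with
  advice to use more controls or a smaller `k`.

**Negative controls.** The design deliberately avoids housekeeping genes
and spike-ins. Controls must carry unwanted (cartridge) but not
biological variation, so they are chosen as the `ceiling(fraction · p)`
genes with the *lowest between-biological-unit variance* of
replicate-averaged log expression, restricted to genes expressed above a
floor (`lod`, default 0 on the log2 scale) in at least half the samples.
The default fraction is 0.2; ties are broken by probe name so selection
is deterministic. The exact variance statistic used in practice by any
given lab is a configuration matter, which is why both the fraction and
the floor are arguments and the chosen controls are recorded in the
normalization model and the CLI manifest.

**Choosing k.** One dominant cartridge factor is the typical failure
mode, so the default is `k = 1`. Because the right `k` is ultimately an
empirical question, `ruv3_k_sweep()` reports the median and mean
absolute replicate log difference for `k = 0 … min(5, n − rank(M))`;
replicate agreement approaching zero without collapsing biological
signal is the criterion a user should apply.

## FSQN

Feature-specific quantile normalization maps each gene of the panel
matrix onto the same gene's distribution in the reference cohort: for a
gene with `n` test values, the target's values are summarized by `n`
linearly interpolated quantiles (the common type-7 convention) and
assigned in rank order. Tied test values receive the mean of their
mapped quantiles, making the map deterministic. Consequences worth
knowing: within each gene the output multiset equals the target
quantiles exactly, ranks are preserved, the operation is idempotent, and
a constant target gene collapses the panel gene to that constant.

## Subtype classification

The original study applied previously trained machine-learning models
whose coefficients are not restated anywhere we can consume; the
classifier is therefore re-implemented as L2-regularized (ridge)
multinomial logistic regression on the scheme's panel genes — 57 genes
for the TCGA scheme (CIN/EBV/GS/MSI), 50 for the binary TME score —
with:

* regularization strength chosen by 5-fold cross-validation on deviance,
  with *class-stratified* folds (EBV-type tumours are ~5% prevalent;
  unstratified folds can starve a training fold of a rare class);
* inverse-frequency class weights for the same reason;
* the softmax link providing calibrated per-class probabilities. Whether
  the original "subtype scores" were softmax probabilities or ensemble
  vote fractions is not documented; the probabilistic interpretation is
  adopted because it yields scores in [0, 1] that sum to one and average
  meaningfully across replicates.

Technical replicates are averaged at the *score* level within each
biological unit and the discrete call is the argmax of the averaged
scores (for the binary TME scheme this is the 0.5 threshold; no bespoke
cut-point is used). Exact ties are broken by class-name order and
surfaced as a message.

## MSI calling and concordance

The pentaplex rule is purely count-based: allelic variation at ≥ 2 of
the 5 mononucleotide markers is MSI-High, exactly 1 is MSI-Low, 0 is
MSS. When PCR calls are compared with the expression classifier, the
classifier has a single MSI class, so MSI-Low is binarized to "not MSI";
this mapping is a documented convention of the comparison, not of the
rule itself.

## Dose–response and DSS

Inhibition (`100 − viability`) is fit against x = log10 molar
concentration with the 4PL curve
`y(x) = a + (d − a)/(1 + 10^{h (x50 − x)})` by Levenberg–Marquardt least
squares from a deterministic multi-start grid (hill slope × IC50
quartiles × two top-asymptote starts). Two numerical choices matter:

* **Physical bounds.** The asymptotes are constrained to the percentage
  range (`a ∈ [0, 90]`, `d ∈ [10, 100]`). The unconstrained 4PL is
  weakly identified when a plateau is not sampled by the dilution grid:
  the top asymptote trades off against the IC50 and can drift far above
  100% inhibition, which is not physically meaningful for
  vehicle-normalized viability. Starts are kept strictly inside the
  bounds because LM stalls when initialized on a box constraint.
* **Degenerate curves.** A response with (near-)zero variance is
  returned as a flagged flat fit rather than an error, and scores zero
  DSS when it never exceeds the activity threshold.

Fit quality is the adjusted R² with 4 parameters. The built-in dose
grids reproduce the assay design: 8 half-log dilutions from 800 µM
(5-fluorouracil) and 2400 µM (oxaliplatin), ten-fold dilutions from
2400 nM (docetaxel); combination (FLOT) curves are fit against the
5-fluorouracil concentration axis with companions co-varying by the
dilution design and the constant leucovorin dose excluded from the axis.

DSS integrates the fitted inhibition curve above an activity threshold
`t` (default 10%, the cited scoring method's convention) over the tested
window `[x1, x2]`:
`I = ∫_{x1c}^{x2} (y(x) − t) dx` with `x1c` the larger of `x1` and the
threshold crossing. The 4PL has an analytic antiderivative in log10
space, so the integral is computed in closed form and cross-checked
against adaptive quadrature at every call (tolerance 1e−6);
`DSS1 = 100·I/((100 − t)(x2 − x1))`, `DSS2 = DSS1·100/d`,
`DSS3 = DSS2·(x2 − x1c)/(x2 − x1)`. All three variants are reported;
DSS2 is the conventional headline. Inhibition (not viability)
orientation is used throughout. Note that `DSS2 ≥ DSS1` whenever
`d ≤ 100`: the top-asymptote normalization rescales partial responders
upward, and only `DSS3 ≤ DSS2` holds universally.

## Comparison statistics

Conventions, chosen once and used everywhere:

* **Wilcoxon tests** (paired signed-rank and two-group rank-sum) use the
  exact distribution for ≤ 25 untied observations — the study's n = 11
  organoid pairs sit squarely in the exact regime — and a normal
  approximation with continuity correction otherwise. Zero paired
  differences are dropped (signed-rank convention); an all-zero
  difference vector is degenerate and reported as p = 1 with a flag.
* **Chi-square** comparisons of class proportions are uncorrected
  Pearson tests (no continuity correction); an expected-count validity
  flag is reported rather than silently switching tests.
* **Multiplicity**: Benjamini–Hochberg across panels/drug screens;
  Bonferroni for Dunn's post hoc pairwise tests after Kruskal–Wallis,
  matching the pooled drug-target analysis. Dunn's z-tests use rank sums
  from the pooled ranking with tie correction.
* **Drug association**: drugs with > 25% missing sensitivity values are
  removed before correlation; per-drug Pearson r (two-sided t
  approximation) against each subtype score, then r values pooled by
  target pathway.

## Over-representation analysis

ORA is the upper-tail hypergeometric test `P(X ≥ x)` with universe size
N, set size K, query size n and overlap x, BH-adjusted across the
collection. The universe defaults to the genes the caller actually
measured (the panel), *not* the genome: ORA p-values depend strongly on
the universe and a whole-genome universe would overstate enrichment for
a 50-gene query. The enrichment network takes the top 15 significant
sets (ties by raw p then name), connects them to their member query
genes, and ranks hub genes by degree; the force-directed layout is
seeded and purely presentational.

## The synthetic-data generator

`sim_config()` encodes the emulated study design: 38 biological units on
a 107-gene panel, 7 units in technical duplicate placed on different
cartridges, 3 cartridges with a one-dimensional batch factor of 1 log2
unit, class-marker blocks of 10 genes shifted by 2 log2 units, log2
noise sd 0.25, and reference-cohort class prevalences matching the
public-cohort mix (CIN 74.1%, EBV 5.6%, GS 8.6%, MSI 11.7%,
renormalized). The default reference size is 400 samples — large enough
to train a stable ridge classifier on 107 genes while keeping the test
suite and acceptance runs compact; the public cohort it stands in for is
an order of magnitude larger, and `ref_n` scales up freely. Count noise
is log-normal (Gaussian on the log2 scale) rather than negative
binomial: the pipeline operates entirely on log2 values and no
count-level dispersion estimates are available to calibrate a negative
binomial. Dose–response plates add Gaussian viability noise (sd 5%) in
triplicate on the assay grids.

What the generator does *not* emulate: gene–gene correlation beyond
class structure, FFPE degradation gradients, probe-level biases,
lane-position effects, or any real biology of gastric cancer expression.
Passing recovery tests therefore demonstrates that the estimators do
what they claim under their own assumptions — planted factors are
removed, planted classes are recovered — not that real tumours will be
classified with the same accuracy.

The paired tumour/organoid fixture defaults to 11 pairs with 9
TME-concordant and 7 TCGA-concordant pairs, the configuration of the
study cohort, with discordant organoids drifting toward CIN/TME Low as
observed in culture.

## Problem sizes and limitations

The shipped tests and the acceptance script use: 20 random RUV-III
instances (n ≤ 30, p ≤ 120) against a step-by-step linear-algebra
oracle; 10 seeded panel runs for batch-removal recovery; 50 random
matrices for FSQN exactness; a 400-sample reference and 40-unit panel
for end-to-end recovery; all 32 pentaplex profiles; 200 noisy
dose–response curves for IC50 recovery; and exhaustive enumeration
oracles for the hypergeometric and exact Wilcoxon distributions at small
n. These sizes were chosen as the smallest that exercise every code path
convincingly.

Known limitations: the classifier is not the original study's trained
model (its coefficients are unavailable), so absolute subtype scores are
not comparable with published scores, only the methodology is; QC
thresholds are instrument-manual defaults rather than a fitted policy;
RUV-III assumes the replicate design spans the unwanted factors (a
cartridge with no replicate sample on it is invisible to the estimator);
and the CCLE/GDSC association module consumes externally prepared AUC
tables rather than recomputing drug sensitivity from raw screens.
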