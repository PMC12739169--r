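---
title: "Models and methods behind ovasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ovasig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovasig)
```

`ovasig` implements a chain of analyses for high-grade serous ovarian
cancer (HGSC) transcriptomics: single-sample molecular subtyping by
preranked GSEA with a delta-NES ambiguity filter, z-score signature scoring
with ROC evaluation, tumor–immune marker metrics with random-effects
pooling of correlations, and dose–response synergy quantification. This
vignette explains each model, the parameters that matter, the numerical
conventions, and what the synthetic generators do and do not emulate.

## Single-sample preranked GSEA

### Ranking metric

A sample `s` is ranked against its own cohort: for each gene `g`,

    score_g = log2( (x_gs + c) / (median over samples of x_g + c) )

on the linear expression scale (log2 input is de-logged first). The
pseudocount `c` (default 1) guards zeros; the default suits count/TPM-like
magnitudes. The cohort median is robust to the subtype composition as long
as no single subtype exceeds half the cohort — an important practical
limit: in a cohort dominated by one subtype the median absorbs that
subtype's shift and the metric loses its signal. Ties in the ranking are
broken by gene identifier (C-locale ascending) so results are
platform-reproducible. The same metric is used for tumor samples and cell
lines; nothing in the pipeline distinguishes the two, and a single ranking
convention keeps NES values comparable across uses.

### Enrichment score

The classic weighted Kolmogorov–Smirnov running sum over the ranked list:
hits advance by `|r|^p / Σ_hits |r|^p`, misses retreat by `1/(N − N_hits)`,
and ES is the signed maximal deviation from zero. `weight_p = 1` by
default (the standard weighted statistic); `p = 0` gives the unweighted KS
statistic. The running sum necessarily returns to zero, ES lies in
[−1, 1], and a near-tie between the positive and negative extremum
(within 1e−9) resolves to the positive one so the sign is stable under
floating-point reordering. Genes in a set but absent from the matrix are
intersected out; sets below `min_set_size = 5` after intersection are
rejected rather than scored.

### Permutation normalization

NES uses gene-set permutation — `n_perm` (default 1000) uniform random
subsets of the same intersected size scored on the same ranked list — not
phenotype permutation, because classification operates on one preranked
sample at a time and there is no phenotype axis to permute. Following the
standard GSEA convention, normalization and the p-value condition on the
sign: `NES = ES / mean(|ES*|)` over same-sign permutations, and
`p = (1 + #{|ES*| ≥ |ES|, same sign}) / (1 + #same-sign)`, never exactly
zero. Note a consequence worth knowing: only about half of random subsets
share a given sign, so the attainable p-value floor is roughly
`2/n_perm`, and the result records `n_same_sign` to make the floor
explicit. A second consequence: a sample with extreme outlier scores
inflates its own permutation null (random subsets catch the outliers), so
NES is deliberately conservative for such samples.

Within one sample the permutation null depends only on the ranked list and
the intersected set size, so the classifier computes one null per distinct
size and shares it across signatures — several-fold faster when signatures
share a size, with an identical distribution.

## Subtype classification and the delta-NES filter

Each sample gets one NES per subtype signature; the call is the
argmax-NES subtype. The margin between the highest and second-highest NES
(delta-NES) drives the ambiguity rule: a sample with margin below the
cutoff (default 0.4) is effectively assigned to more than one cluster and
is excluded. The top-two margin is the minimal reading of a single scalar
cutoff; alternatives (e.g., counting all subtypes within the cutoff of the
top) collapse to the same decision for the exclusion question. Samples
whose best NES is not positive are also excluded — no subtype is
positively enriched, so no call is defensible. Signatures are UP-only
gene sets supplied as GMT input; the signature lists shipped by the
generators are synthetic ground truth, and real subtype signatures are a
user input. Per-sample RNG seeds are derived from the cohort seed and a
hash of the sample identifier, so cohort results are invariant to column
order and reproducible sample-by-sample.

`apply_delta_cutoff()` re-applies the filter to an existing NES table
without re-running GSEA; the exclusion fraction is non-decreasing in the
cutoff by construction, and the tests assert it.

## Z-scores, signature scores and ROC

Z-transformation standardizes each gene with the sample standard deviation
(denominator n − 1); the choice is pinned by tests. Constant genes carry
no information and are dropped with a warning. A signature score is the
mean z over the signature genes present; missing genes are dropped and
reported, never imputed — the intersect-and-score behavior of standard
signature tools, kept auditable.

AUC is computed as the tie-corrected Mann–Whitney statistic via midranks
(`U/(n⁺n⁻)`, ties counting ½), which equals the trapezoidal area under the
ROC curve built from all distinct thresholds; the suite asserts both
routes agree to 1e−12 and cross-checks pROC. The positive class is the
signature's direction (C5-like, signature-high). A stratified bootstrap CI
(`roc_auc_ci()`, 2000 seeded resamples) is available for comparing
classifiers; it is off the default path because the headline use is a
single AUC.

## Immune metrics and correlation pooling

Cumulative marker scores are plain sums of linear-scale expression over a
panel, per column; the MHC-I/PD-L1 ratio is
`log2((Σ MHC-I + ε)/(PD-L1 + ε))` with a shared pseudocount ε = 1 by
default, because count data contain zero denominators and the ratio must
stay finite. Default panels are human class-I HLA (HLA-A/B/C) over CD274;
identifiers match case-sensitively and are never mapped across species, so
murine panels are supplied as separate sets. The per-cell output tibble
aggregates to per-cluster summaries by ordinary grouping, covering both
granularities since the choice between them is analysis-dependent.

Pearson correlations use the product-moment formula with the parametric
two-sided t test on n − 2 degrees of freedom; |r| = 1 is flagged and
returns p = 0 rather than an undefined t. Pooling across datasets is
DerSimonian–Laird on the Fisher-z scale: z = atanh(r), variance 1/(n − 3),
fixed weights w = n − 3, Cochran `Q`, `τ² = max(0, (Q − df)/C)` with
`C = Σw − Σw²/Σw`, random-effect weights `1/(v + τ²)`, and
`I² = max(0, (Q − df)/Q)·100`. DL-on-z is the classic closed-form default
of the standard meta-analysis tooling and is fully testable by a longhand
worksheet; the suite also cross-checks metafor. One property worth
flagging: duplicating a study does *not* monotonically shrink τ² under DL
(Q, df and C all move), so no such invariant is asserted — the asserted
properties are the degenerate identities (single study, exact
homogeneity) and that the pooled r stays within the study range.

## Dose–response synergy

The 4PL model is `v(c) = bottom + (top − bottom)/(1 + (c/EC50)^hill)` with
viability as a fraction of vehicle control (the fitter never
renormalizes). Initialization is deterministic: top/bottom from the
extreme per-concentration means, EC50 from linear interpolation of the
half-range crossing on log10 concentration (geometric center fallback if
no crossing exists), hill = 1. Refinement is bounded Levenberg–Marquardt
least squares on log10(EC50) — chosen over a derivative-free search
because it is the standard, fast and equally deterministic route (no
random restarts) — with box bounds: bottom ∈ [0, top estimate],
hill ∈ (0, 10], and EC50 constrained to the tested range extended one
dilution step per side, so an extrapolated potency can never be reported.
Flat data are rejected as "no dose response".

The synergy indices are deliberately simple ratios. The combination index
`CI = a/A + b/B` compares each agent's effective level in the combination
(`a`, `b`) to its single-treatment EC50 or fixed dose (`A`, `B`); it is
unit-free given per-drug unit consistency (enforced when units are
supplied, and checked by a rescaling-invariance test). The coefficient of
drug interaction `CDI = AB/(A·B)` compares the combination viability to
the Bliss-independence product of the single-treatment viabilities. Both
indicate synergy below 1. CDI takes viabilities directly because published
EC50 tables rarely include them; the dose–response table route can supply
them at a named concentration pair. Reported values are full precision;
only the print layer rounds (CI/CDI to 2 decimals, fold change to the
nearest integer), matching how such values are conventionally printed.

## Synthetic generators: what they emulate

All generators are pure functions of their arguments and a seed.

* `simulate_subtype_cohort()` emulates a four-subtype HGSC cohort in log2
  space: per-gene baselines uniform on [3, 8] (typical log2 expression),
  disjoint signature blocks shifted by `effect_size` in their own subtype,
  Gaussian noise. Defaults — 40 samples per subtype, 1000 genes, 50-gene
  signatures, shift 2, noise sd 1 — are the configuration the recovery
  analyses use throughout; subtype proportions are uniform by default
  (real C5 prevalence is a minority; pass skewed `n_per_subtype` to
  emulate that). The 8-gene oncofetal-RBP set heads the C5 block under its
  canonical symbols, giving a ground-truth C5-vs-rest signature. Gaussian
  log-space noise is chosen because every downstream step ranks or
  z-scores (distribution-light), and it keeps closed-form expectations
  available — e.g., the signature AUC converges to
  `Φ(δ√m/(σ√2))`, which the suite checks at n = 5000/group.
* `simulate_cell_population()` draws negative-binomial counts around
  cluster-specific mean profiles scaled to a common library size, with a
  single shared dispersion — the simplest overdispersed model adequate for
  ratio metrics. `cell_population_means()` builds mean profiles around a
  target MHC-I/PD-L1 ratio per cluster.
* `simulate_dose_response()` draws 4PL viabilities with Gaussian noise
  truncated at 0 on a geometric concentration series. The default curves
  are the combination experiment's configuration: antibody mono EC50
  87.7 ng/mL, combo 5.3 ng/mL (17-fold potentiation by a fixed 5 µM
  partner dose; the partner's own EC50 8.6 µM), top 1, bottom 0.05,
  hill 1, 8 doses × 3 replicates, noise sd 0.02.

What they do not emulate: batch effects, dropout, realistic scRNA-seq
depth profiles, correlated genes, or non-Gaussian expression noise. A
passing recovery test therefore shows the pipeline is correct under its
own assumptions — it does not certify performance on real cohorts, where
signature quality and cohort composition dominate.

## Problem sizes and numerical conventions

The test and acceptance runs use the generator defaults above: the
classifier-recovery analysis runs 160 samples × 1000 genes at 1000
permutations; null-calibration draws 200 permutation p-values at 10,000
permutations each on a 1000-gene list; 4PL recovery fits 100 noisy
simulations; ROC convergence uses 5000 samples per group. These sizes give
stable Monte-Carlo behavior while keeping a full run in minutes on one
core. Oracle comparisons are pinned at 1e−12 (pure arithmetic), the
meta-analysis worksheet at 1e−8, and distributional checks use fixed seeds
with non-marginal thresholds.

## Known limitations

* Real subtype signature lists are not shipped; classification quality on
  real cohorts depends entirely on the supplied GMT.
* The ranking metric assumes the cohort median is a meaningful reference;
  single-subtype or heavily skewed cohorts violate this.
* CDI is only as good as the viability normalization feeding it.
* No FDR across many gene sets (the classifier consumes NES directly), no
  leading-edge reporting, no isobologram/Bliss-surface analysis beyond the
  two indices, and no survival analysis.
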