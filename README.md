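# ovasig

Molecular subtyping, gene-signature scoring and drug-synergy analysis for
high-grade serous ovarian cancer (HGSC) transcriptomics.

HGSC tumors fall into transcriptome-defined molecular subtypes — C1
(mesenchymal), C2 (immune-reactive), C4 (differentiated) and C5
(proliferative, immune-evasive) — and the C5 state is marked by re-expressed
oncofetal RNA-binding proteins (DDX25, ELAVL3, IGF2BP1, IGF2BP3, LIN28B,
MEX3A, MKRN3, MSI1) and a low MHC-I/PD-L1 surface-receptor balance. `ovasig`
implements the computational chain used to work with these states, end to
end and fully testable on synthetic data:

* **Single-sample preranked GSEA subtyping.** Each sample is ranked by
  `log2((x_gs + c) / (median_s' x_gs' + c))` against the cohort median; each
  subtype signature gets a weighted Kolmogorov–Smirnov enrichment score
  (hit step `|r|^p / Σ_hits |r|^p`, miss step `1/(N − N_hits)`, ES = signed
  maximal deviation) normalized against a gene-set permutation null
  (`NES = ES / mean |ES*|` over same-sign permutations). The call is the
  argmax-NES subtype; samples whose top-two NES margin (delta-NES) falls
  below 0.4 are ambiguous and excluded, as are samples with no positive
  enrichment.
* **Signature scoring and ROC.** Per-gene z-transformation (sample sd),
  mean-z signature scores, and tie-corrected Mann–Whitney AUC
  (`U/(n⁺ n⁻)`, ties = ½) with the full ROC curve.
* **Tumor–immune metrics.** Cumulative marker-panel scores, the
  `log2((ΣMHC-I + ε)/(PD-L1 + ε))` ratio, Pearson correlation with the
  parametric two-sided t test, and DerSimonian–Laird random-effects pooling
  of correlations on the Fisher-z scale with Cochran Q, τ² and I².
* **Dose–response synergy.** Four-parameter logistic fits
  `v(c) = bottom + (top − bottom)/(1 + (c/EC50)^hill)` with deterministic
  initialization and bounded least squares; EC50 fold change; the
  combination index `CI = a/A + b/B` and the coefficient of drug
  interaction `CDI = AB/(A·B)`, with synergy indicated by values < 1.
* **Synthetic-data generators** for subtype cohorts, clustered
  negative-binomial cell populations and 4PL titrations, so every stage
  runs without external cohorts.

Everything is tidyverse-shaped: tibbles in and out, `tidy()`/`glance()`
methods on every fitted object, `autoplot()` for ROC curves, dose–response
fits, forest plots and subtype frequencies.

## Worked example

```r
library(ovasig)

# A synthetic 160-sample cohort in the default configuration:
# four subtypes, 50-gene signatures, +2 log2 signature shift over N(0,1) noise
sim <- simulate_subtype_cohort(seed = 1)
cc  <- classify_cohort(sim$matrix, sim$signatures[c("C1", "C2", "C4", "C5")],
                       delta_cutoff = 0.4, n_perm = 1000, seed = 1)
glance(cc)
#> # A tibble: 5 × 3
#>   label        count frequency
#>   <chr>        <int>     <dbl>
#> 1 C1              40    0.25
#> 2 C2              40    0.25
#> 3 C4              40    0.25
#> 4 C5              40    0.25
#> 5 unclassified     0    0

# The embedded 8-gene oncofetal-RBP signature as a C5 classifier
sc  <- signature_score(zscore_transform(sim$matrix), sim$signatures$RBP)
roc <- roc_auc(sc, setNames(sim$labels$subtype == "C5", sim$labels$sample_id))
glance(roc)
#> # A tibble: 1 × 3
#>     auc n_pos n_neg
#>   <dbl> <int> <int>
#> 1     1    40   120

# Synergy from the published EC50 values: antibody mono 87.7 ng/mL,
# combo 5.3 ng/mL; partner mono EC50 8.6 uM, fixed combo dose 5 uM
combination_index(A = 87.7, a = 5.3, B = 8.6, b = 5,
                  unit_1 = "ng/mL", unit_2 = "uM")
#> <synergy_result> CI = 0.64 (synergy), EC50 fold change = 17
```

At this effect size the classifier recovers every generated label and the
RBP signature separates C5 from non-C5 perfectly; the CI below 1 quantifies
the potentiation of the antibody by the fixed-dose partner (a 17-fold EC50
drop, 36% more inhibition than an additive expectation).

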