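---
title: "Developing a radiomic signature for small renal masses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing a radiomic signature for small renal masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small renal masses (SRMs, renal tumors under 4 cm) detected on
contrast-enhanced CT are often resected without a confident preoperative
benign/malignant call; a substantial minority turn out to be benign
(oncocytomas, lipid-poor angiomyolipomas, leiomyomas). Radiomics offers a
non-invasive discriminator: quantitative features (first-order intensity
statistics and texture-matrix descriptors such as GLCM, GLRLM, GLSZM,
NGTDM, GLDM) computed from the segmented lesion volume in the portal
venous phase. `radsig` implements the full signature-development pipeline
downstream of feature extraction: it consumes a patient-by-feature table
with an outcome label and per-patient CT acquisition metadata, and
produces a compact feature signature with a tuned k-nearest-neighbour
classifier and stability estimates for every performance metric.

Image segmentation and feature extraction themselves are out of scope:
those are performed by established tools and the package starts from
their tabular output.

## Pipeline overview

1. **Stratified 80/20 split** into a training set and a held-out test set,
   balanced on the outcome.
2. **Feature-selection MCCV** (Monte Carlo cross-validation, default 100
   rounds). Each round draws a stratified 80/20 subset of the training
   set and, on the 80% part, runs: redundant-feature elimination
   (|Pearson r| > 0.99), z-score standardization, Random Walk Oversampling
   (RWO) of the minority class to parity, the acquisition-reproducibility
   chain, and a Mann-Whitney test of each surviving feature against the
   outcome. A feature scores one point per round in which it survives
   preprocessing and achieves p < 0.05; the 10 highest cumulative scores
   form the signature.
3. **Model tuning** by a second MCCV: PCA or ICA to d = 2 or 3 components
   followed by kNN (odd k from 3 to 15), scored by mean validation F1 of
   the minority (benign) class, with common per-round seeds so the grid
   comparison is paired.
4. **Final evaluation**: the tuned model is retrained per round and scored
   on the untouched 20% validation subset and on the fixed test set;
   means and standard deviations over rounds quantify stability.

All preprocessing is fitted on the round's training part only and
transferred unchanged to anything scored later; oversampling is never
applied to validation or test data.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `test_fraction` | 0.2 | held-out share of the cohort |
| `redundancy_threshold` | 0.99 | \|r\| above which a feature pair is redundant |
| `alpha` | 0.05 | level of the Kruskal-Wallis and Mann-Whitney tests |
| `rho_threshold` | 0.75 | \|Spearman rho\| above which a feature tracks a continuous acquisition parameter |
| `fs_rounds`, `train_rounds` | 100 | MCCV depth of the two steps |
| `signature_size` | 10 | features kept after scoring |
| `d_values`, `k_values` | {2,3}, odd 3-15 | tuning grid |

The defaults are the constants of the clinical study the pipeline
implements; `model_config()` defaults to its tuned optimum (PCA, d = 2,
k = 7).

Per-class test counts in stratified splits are rounded class shares
reconciled by largest remainder, which reproduces the 51/34 cohort's
17-patient test set (10 malignant, 7 benign) at a 0.2 fraction.

## The reproducibility chain

Radiomic features can track the scanner rather than the tumor. Five tests
run per feature in fixed order: Kruskal-Wallis against scanner model
(n.1) and convolution kernel (n.2), then Spearman correlation against
pixel spacing (n.3), slice thickness (n.4) and tube voltage (n.5). A
feature is removed at the first failing test (KW p < 0.05 or |rho| >
0.75) and attributed to that parameter only. Raw thresholds are used
deliberately - no multiple-testing correction - because the chain is a
conservative screen: over-removal costs features, under-removal risks a
scanner-driven signature. Continuous parameters are tested on their raw
values. Because kernels are nested within scanner models in practice,
test n.1 tends to absorb kernel-confounded features and test n.2 removes
only a few percent more.

Synthetic (oversampled) rows carry no acquisition metadata, so the chain
always runs on the real training rows only. The chain runs afresh in
every MCCV round on that round's subset, which is why the number of
features surviving to selection varies from round to round; a one-shot
global screen can be had by calling `reproducibility_chain()` on the full
training set directly.

## Random Walk Oversampling

The minority class is expanded by perturbing real rows:
`x'_j = x_j - (sigma_j / sqrt(m)) * r_j` with `m` minority rows,
`sigma_j` their population standard deviation and `r_j` standard normal.
Synthetic rows preserve the minority mean, and their per-feature variance
is `sigma_j^2 (1 + 1/m)` - slightly inflated, shrinking as the minority
grows. The tests verify both moments against these closed forms.
Features constant in the minority stay constant (zero step). Oversampled
rows are flagged `.synthetic` and never leave the training subset.

## Numerical and design choices

- **Redundancy drop rule.** For a redundant pair the lexicographically
  later feature name is dropped; deterministic and row-order invariant.
  |r| is used, since perfectly anti-correlated features are equally
  redundant. Zero-variance features are removed at this stage (with a
  distinct report entry) rather than erroring a whole MCCV round.
- **Mann-Whitney.** U is computed from rank sums; p is exact (via the
  null U distribution) for pooled n <= 20 without ties, else the
  tie-corrected normal approximation. The filter sees the balanced
  subset, matching the stated preprocessing order; `mw_on_balanced =
  FALSE` reruns it on real rows as a sensitivity analysis.
- **Scoreboard semantics.** A feature removed by preprocessing in a round
  scores 0 for that round; cumulative score is comparable across
  features because the denominator (rounds) is common. Ties at the
  signature cut break by ascending mean Mann-Whitney p, then name.
- **PCA/ICA determinism.** PCA takes leading covariance eigenvectors;
  ICA whitens to d components and runs symmetric fixed-point FastICA
  (logcosh) under a fixed seed, with components reordered by explained
  variance. Both fix each component's sign so its largest-magnitude
  loading is positive, making transforms reproducible and replays
  byte-identical.
- **kNN.** Euclidean distance in component space; the malignancy score
  is the malignant fraction among the k nearest references; odd k
  precludes vote ties and exact distance ties break by reference
  insertion order (stable radix ordering).
- **Metric conventions.** Sensitivity, specificity, PPV and NPV treat
  malignant as positive; F1 treats benign - the minority - as positive.
  This is the one assignment consistent with the prevalence arithmetic
  of the reported metrics. ROC-AUC is the normalized Mann-Whitney U of
  the scores (ties half-weighted), asserted against brute-force pair
  counting in the tests.
- **Tuning tie-breaks.** Equal mean validation F1 resolves to smaller d,
  then smaller k, then PCA over ICA - the simpler, more explainable
  model.
- **Seeds.** Every stochastic step accepts a seed; MCCV round r runs
  under `base_seed + r`, and the pipeline derives its five stage seeds
  from one base seed. A run's manifest suffices to replay it exactly.

## The synthetic cohort generator

Real patient data for this problem are not redistributable, so the
generator emulates the statistical structure the pipeline must handle,
with defaults matching the study conditions: 85 patients (51 malignant:
37 clear cell, 7 chromophobe, 7 papillary; 34 benign: 25 oncocytoma, 7
lipid-poor AML, 2 leiomyoma), 107 features, three scanner models with
nested kernel subsets (B31s, B40s, B20f, B30f, Br32f), pixel spacing
0.61-0.98 mm, slice thickness 1.5-2.5 mm, tube voltage 100-130 kVp.
Planted structure:

- 14 redundant triplets (noise sd 0.05 around an anchor, pairwise
  r ~ 1/(1 + sd^2) > 0.99) - about 26% of features, matching the
  redundancy fraction the pipeline is expected to remove;
- 24 scanner-batch-affected features with additive per-scanner shifts
  2 sd apart - about 30% of the non-redundant features fail test n.1;
- 5 class-informative features at a standardized mean difference of 1.5,
  a realistically strong radiomic effect;
- the rest pure noise.

Batch effects are additive (the simplest mechanism the KW test detects),
and continuous metadata are independent of the class label, so
reproducibility filtering and outcome signal stay orthogonal unless the
user couples them. What the generator does **not** emulate: the heavy
mutual correlation structure of real texture features (beyond the planted
blocks), non-Gaussian marginals, and any genuine scanner-outcome
confounding. Passing tests on synthetic cohorts therefore demonstrate
that the machinery is correct and calibrated, not that any particular
clinical performance level will be attained on real data.

## Known limitations

- **Stability scores under the null are not binomial.** MCCV rounds
  resample one fixed training set. A feature that by chance associates
  with the outcome in that sample (and with ~100 features at n ~ 70 the
  strongest chance association is typically |r| ~ 0.3-0.45) passes the
  per-round filter in most rounds, so its cumulative score approaches
  the round count even with no true effect. Cumulative scores rank
  features well - planted informative features reliably out-rank chance
  associations - but the absolute score is not a significance measure,
  and label-permutation runs of the whole pipeline (where test AUC falls
  to ~0.5) are the honest null calibration.
- Oversampling before the univariable filter inflates its effective
  sample size; the balanced-filter behaviour mirrors the published
  procedure, and the `mw_on_balanced = FALSE` option quantifies the
  effect.
- PPV/NPV are undefined (reported `NA`) in rounds where no patient is
  predicted into the respective class; summary means skip them.
- The feature count is data-driven throughout; nothing assumes 107.

## Problem sizes used by the checks

The packaged checks run the MCCV steps at 25 rounds (and smoke tests at
5-10) rather than the production default of 100; cumulative-score
thresholds scale with the round count, and all structural conclusions
(counts, calibration, recovery, determinism) are round-count invariant.
The acceptance script likewise runs 25 + 25 rounds.
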