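---
title: "Methods: simulating and classifying small hypoattenuating hepatic nodules"
author: "hepanode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying small hypoattenuating hepatic nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepanode)
```

## The problem

On contrast-enhanced CT of colorectal-cancer patients, small (<10 mm)
hypoattenuating hepatic nodules — darker than the enhanced liver but not of
water attenuation — are common and frequently "too small to characterize"
visually. The clinical question is binary: is such a nodule a benign finding
or a metastasis? This package implements, end to end, a pipeline for that
question: a convolutional patch classifier trained under patient-grouped
cross-validation, fused with one clinical covariate (the presence of a
synchronous, definitive ≥1 cm liver metastasis on the same scan) through a
two-variable logistic model, and evaluated with the nonparametric
diagnostic-statistics stack standard in reader studies.

Because no clinical CT cohort of this kind is publicly available, the
package is built around a synthetic cohort generator whose statistical
structure mirrors the clinical setting. Every downstream stage — training,
fusion, evaluation, interpretability — runs identically on real patch
tables and arrays, should they exist; the generator is what makes the whole
chain testable.

## The synthetic cohort generator

`simulateCohort()` draws a three-level hierarchy:

* **Patients** carry a Bernoulli synchronous-liver-metastasis indicator
  (prevalence 0.244 by default, the X2 covariate), an independent
  extrahepatic-metastasis indicator (prevalence 0.122) that serves as a
  null candidate for predictor screening, and 1–6 nodules. Nodule counts
  are zero-truncated Poisson with the rate solved so the *uncapped* mean
  equals `meanNodulesPerPatient` (default 2.75), then capped at 6 —
  mirroring the selection rule that at most six nodules per patient enter
  the analysis.
* **Lesions** get a benign/malignant label. The malignancy probability is a
  logit-linear function of the patient's X2: the log-odds shift is
  `log(liverMetOddsMultiplier)` (default `log 8`), and the intercept is
  solved numerically so the marginal malignant fraction equals
  `malignantFraction` (default 0.342). This gives the combined logistic
  model a known generative ground truth.
* **Patches**: each lesion contributes `1 + Poisson(mean - 1)` slices
  (default mean 3.32), each an independent 32×32 render with fresh noise
  and a radius shrink factor drawn from U(0.8, 1) for non-central slices
  (nodules narrow toward their poles).

### Rendering and phenotypes

A nodule is rendered on an enhanced-liver background of ~100 HU-like units
(the attenuation *scale* is arbitrary; only contrasts matter downstream,
and portal-venous liver sits near +100 HU). The radial profile is a blurred
step: pixel intensity is `background − depth · Φ((r_b(θ) − r)/σ)`, where
`r_b(θ)` is the boundary radius, `σ` the edge blur, and Φ the normal CDF.
The binary ground-truth mask is the un-blurred footprint `r ≤ r_b(θ)`;
masks are carried as ground truth rather than re-segmented, since manual
ROIs are not reproducible anyway. Boundary irregularity modulates `r_b`
with a random harmonic series (orders 2–5), normalized so the relative
modulation amplitude equals the `boundaryIrregularity` parameter and
clamped at 0.3·radius so the mask stays star-shaped, hence connected.
Nodule cores are kept above water attenuation, and a render whose mask
would touch the patch border raises an error.

Class differences follow the four directions observed on real nodules —
malignant nodules are larger, closer to liver attenuation (smaller depth),
blurrier, and less solid. Since published evidence fixes only the
*ordering* of these distributions, the effect sizes are configuration
knobs: a single multiplier, `phenotypeGap`, scales all four class shifts
(radius +1.8·gap px, depth −12·gap HU, blur +1.0·gap px, irregularity
+0.25·gap). The default gap of 1 produces a realistically hard problem
(CNN lesion AUC well below 1); gap 2 produces a strongly separated cohort
used for mechanism checks; gap 0 makes the classes identical.

What the generator does **not** emulate: 3-D texture and partial-volume
effects, scanner/protocol variability, anatomical context beyond the patch
(vessels, liver edge), and reference-standard noise (labels are exact).
Tests passing on synthetic cohorts therefore validate the *mechanics and
statistics* of the pipeline, not clinical performance.

### Simulated readers

`simulateReaders()` draws, per reader profile, a correct call with
probability sensitivity (malignant lesions) or specificity (benign) and a
1–5 Likert confidence: with probability `confidenceSpread` the confidence
is uniform on 1–5, otherwise 5. This two-parameter scheme spans the cases
the evaluation code must handle — a perfect, fully confident reader maps
onto ordinals {1, 10} only; a wide-spread reader covers all ten levels.

## Augmentation and balanced epochs

Patches are stored at 32×32 and cropped to 24×24 network inputs, allowing
translation up to 4 pixels per axis with **no interpolation**: every
augmentation output is a pixel rearrangement of its input window. The crop
offsets (9×9) combined with the 8 elements of the dihedral group of the
square give 648 distinct augmentation specs; augmentation order is fixed as
crop → rotate → reflect (a different order only re-parameterizes the same
reachable set). At each epoch, patches are drawn with replacement so
expected class counts equal the originals times the class factors (benign
×2, malignant ×6 by default, matching roughly one-third malignant
prevalence; `malignantFactor = NA` balances exactly at
`2 · n_benign / n_malignant`), each draw receiving an independent uniform
random spec.

## The network and cross-validation

The classifier (`src/cnn.cpp`, im2col + BLAS gemm) is deliberately small:
two 3×3 convolutional layers of 16 filters, 2×2 max-pool, two layers of 32
filters, a second pool, then a 64-unit dense layer flanked by 50 % dropout
and a single sigmoid output; batch size 80 and 50 epochs are the tuned
defaults. Details the original description leaves open are fixed and
surfaced in `trainingConfig()`: ReLU activations, valid convolutions,
binary cross-entropy, Adam at 1e-3, He-normal initialization, and patch
standardization by the cohort mean and SD. All randomness (fold
assignment, initialization, epoch sampling, dropout) derives
deterministically from one seed.

`assignGroupFolds()` partitions **patients**, never lesions: patients are
visited in decreasing patch-count order and greedily assigned to the
lightest fold, which balances patients, lesions and patches simultaneously
and guarantees zero patient leakage between a fold's training and
evaluation sides. Five models are trained, each on four folds; each lesion
is scored by the one model that never saw its patient, and patch
probabilities are aggregated to lesion probabilities by the arithmetic
mean (the simplest permutation-invariant choice; `max` is available). For
external cohorts the five saved models are averaged. Calls threshold at
0.5, with the exact tie resolved to malignant — the sensitivity-favoring
convention for an oncologic screen.

## The combined logistic model

`fitCombined()` estimates `logit(p) = β0 + β1·X1 + β2·X2` by maximum
likelihood, with X1 the CNN lesion probability on its natural [0, 1] scale.
The odds ratio per 10 % increase of CNN probability is therefore
`exp(0.1·β1)` (pre-scaling X1 by 10 would be numerically identical).
Quasi-complete separation is detected and flagged instead of silently
returning divergent estimates — on strongly separated synthetic cohorts
this is the *expected* outcome. `screenPredictors()` performs backward
elimination at α = 0.05, least-significant first (the published analysis
describes a single drop — extrahepatic disease — not an order; an order had
to be fixed and this is the conventional one). Wald CIs are used
throughout.

## Evaluation stack

* **AUC**: Mann–Whitney pair counting (ties one half), computed via
  midranks; the CI uses the DeLong placement-value variance. Paired
  comparisons use DeLong's test, the standard method behind a
  "nonparametric approach" to correlated ROC curves.
* **Threshold metrics** at 0.5: sensitivity, specificity, accuracy as
  percentages with Wald 95 % CIs clipped to [0, 100] (Wilson optional).
* **Agreement**: unweighted Cohen's kappa with the conventional
  interpretation bands (0.41–0.60 moderate, 0.61–0.80 substantial, >0.81
  almost perfect).
* **Ordinal conversions**: benign/confidence c → 6 − c, malignant → 5 + c
  (a bijection onto 1..10); CNN probability → right-closed deciles
  ([0, 0.1] → 1, …, (0.9, 1] → 10; the published bin notation carries
  percent-scale typos and is interpreted as probability deciles). The
  low-confidence zone is ordinals {4, 5, 6, 7}.
* **McNemar**: exact binomial on the discordant pairs when fewer than 25
  are discordant, χ² without continuity correction otherwise.
* The "radiologist mean" comparator is ambiguous in reader studies (mean
  of per-reader AUCs, or AUC of the per-nodule mean score); both are
  computed and labelled (`meanOfAucs`, `aucOfMeanScore`).

## Interpretability

`computeFeatures()` quantifies each patch: **area** (mask pixel count);
**mean central attenuation** over the central 3×3-pixel area — on an
even-sized grid this square straddles pixel boundaries, so it is computed
as the overlap-weighted mean of the central 4×4 block (weights summing
to 9), which makes it exactly invariant under the dihedral transforms;
**edge sharpness** as mean attenuation in the 1-pixel outer margin band
(dilation ring) minus the inner band (erosion ring) — band width
configurable since the original formula is not public; and **solidity** as
mask area over convex-hull pixel area (hull pixels counted by
point-in-polygon over pixel centers, the regionprops convention).
`clusterByProbability()` runs 1-d k-means with seeded k-means++
initialization (10 restarts) and ascending-centroid labels; k defaults
to 5. Class differences are tested per feature with both Welch's t and the
Mann–Whitney test. t-SNE embeds the 64-d dense-layer activations (Rtsne,
perplexity 30 by default, seeded).

## Numerical and design choices, problem sizes

* Stage seeds derive from the global seed by a Lehmer step modulo
  2³¹ − 1, so every derived seed fits an R integer.
* Logistic fits use IRLS via `stats::glm`; coefficients above 15 in
  absolute value are treated as a separation signature.
* The test suite exercises the full chain at sizes chosen to keep a
  complete run to a few minutes on one CPU: mechanism checks use 100
  training patients (≈800 patches) at phenotype gap 2 with 6 training
  epochs (and 3 epochs for permutation-null and low-gap runs), since on a
  strongly separated cohort held-out performance saturates within a few
  epochs; the cap/marginal-rate scans use 500–1500 single-slice patients;
  feature-trend checks pool 20 cohorts of 40 patients. The
  paper-scale protocol (50 epochs, batch 80) remains the package default.
* The feature-trend check sorts lesions into probability clusters using an
  oracle probability fitted from the rendered morphology (logistic on area
  and central attenuation) rather than a freshly trained CNN; this
  isolates the rendering → feature → clustering chain from training noise
  and keeps the check cheap, while the CNN path itself is validated by the
  end-to-end mechanism tests.

## Known limitations

* The architecture details beyond layer counts/widths (activations,
  kernel sizes, optimizer, loss, normalization) are documented defaults,
  not claims about any original implementation.
* Published real-data results (reader AUCs near 0.96, CNN 0.84, combined
  0.95, odds ratios 1.70 and 83.4) depend on an unreleased clinical
  cohort; this package reproduces the *mechanisms* (e.g. the combined
  model's AUC gain over the CNN alone) and the self-contained conversion
  rules and arithmetic, not those numbers.
* Synthetic masks are exact; real manual ROIs carry rater noise that
  would soften the feature-class separations reported by
  `featureClassTests()`.
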