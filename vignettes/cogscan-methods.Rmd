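---
title: "Linking brain volumes to cognitive sub-scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking brain volumes to cognitive sub-scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`cogscan` is an analysis pipeline that connects 3D brain-image volumes (MRI,
FDG-PET, or AV45-PET) to the 13 item scores of the ADAS-Cog13 cognitive
battery. It has seven stages, each a package function driven by a numbered
script under `analysis/`:

1. **simulate** — a seeded synthetic cohort generator (volumes, sub-scores,
   diagnoses, repeat visits);
2. **preprocess** — white-stripe intensity normalization for MRI with QC,
   cohort percentile scaling for PET;
3. **select-subscores** — a random-forest AD-vs-nAD classifier that ranks the
   13 items and selects the diagnosis-relevant subset;
4. **train** — a multi-task 3D convolutional network regressing the selected
   sub-scores from one volume, with best-k checkpoint ensembling;
5. **evaluate** — MAE and R² per sub-score, benchmarked against the
   inter-test variability (ITV) of the scores themselves;
6. **interpret** — atlas-occlusion region importance and Spearman correlation
   of the per-task importance profiles;
7. **diagnose** — a classification extension on the network's
   penultimate-layer embeddings.

Real cohorts of this kind (ADNI-like) are access-controlled, so the package
ships no data; every stage is exercised end to end on the synthetic
generator, whose planted structure makes correctness *testable*: the pipeline
must recover, from volumes alone, which region carries which score.

# The synthetic cohort generator

The generator is first-class, tested code, not a fixture. Its model:

* **Latent severity** $s_i \sim \mathcal N(0,1)$ per subject.
* **Sub-scores.** On each item's min-max scale, the scaled score is
  $u_{it} = \mathrm{clip}_{[0,1]}(0.5 + 0.2\,\lambda_t s_i + \varepsilon_{it})$,
  with loading $\lambda_t = 1$ for the four modelled items (q1, q4, q7, q8)
  and 0 for the other nine, and measurement noise
  $\varepsilon_{it} \sim \mathcal N(0, 0.2)$. Raw scores use the conventional
  ADAS-Cog13 item ranges (word recall items 0–10, orientation 0–8, word
  recognition 0–12, others 0–5); the ranges are configuration, not constants.
  The noise sd of 0.2 scaled units against the severity slope of 0.2 puts the
  pairwise correlation of the informative items near 0.5, in the range
  observed for real ADAS-Cog13 items. This choice matters: were the items
  nearly collinear, any one informative region would suffice to predict all
  four scores and region-to-score attribution would be ill-posed — the
  generator could not serve its validation purpose.
* **Diagnosis.** CN/MCI/AD by thresholding severity at its 33.6% and 78.3%
  quantiles, reproducing the class balance of large AD research cohorts
  (roughly 1/3 CN, 45% MCI, 22% AD). Because the expected total score is
  strictly monotone in severity, this is equivalent to thresholding the
  noiseless total score; crucially it keeps the nine zero-loading items
  uninformative of diagnosis, which the sub-score-selection validation
  requires.
* **Volumes.** The atlas is a centred ellipsoid partitioned into contiguous
  regions by nearest-seed Voronoi assignment. Brain voxels get a
  modality-specific baseline (MRI 100, FDG-PET 6, AV45-PET 1.5), plus, in
  each planted region, $e \cdot u_{it}$ intensity units (the recorded scaled
  score, so each item's unique component lives only in its own region), plus
  i.i.d. Gaussian voxel noise (sd 10 for MRI). The per-voxel effect-to-noise
  ratio $e/\sigma_v$ defaults to 2. Background voxels are 0.
* **Visits.** Each subject receives dated visits scattered uniformly within
  ±91 days of an anchor date; at each visit every score is the base score
  plus $\mathcal N(0, \sigma_{\mathrm{visit}})$ (default 1 raw unit), clipped
  to scale. Dates are ISO-8601 strings; window arithmetic is done in days.
  Visit spacing in real registries is irregular and protocol-specific, so it
  is exposed as configuration rather than asserted.

What the generator does **not** emulate: anatomy (regions are Voronoi cells,
not structures), scanner artefacts, intensity non-uniformity, registration
error, longitudinal disease progression, and site effects. Passing tests
therefore show that the *analysis machinery* is correct and sensitive at the
stated signal-to-noise, not that the model will reach any particular accuracy
on real cohorts.

# Intensity normalization

**White-stripe (MRI).** The normal-appearing white matter (NAWM) is the
high-intensity mode of the brain-voxel histogram on T1 images. We estimate it
by kernel-density peak picking: among density peaks of at least 1/3 the
global peak height, the one at the highest intensity. With $\tau$ the
quantile of that mode, the "stripe" is the voxels between the
$\tau \pm 0.05$ intensity quantiles (the half-width follows the white-stripe
convention; it is configuration). The transform is affine:
$x \mapsto (x - \mathrm{mode})/\mathrm{sd}_{\mathrm{stripe}} \cdot
\sigma_{\mathrm{ref}} + \mu_{\mathrm{ref}}$, applied to brain voxels;
background stays 0, which is also the occlusion fill value. QC re-estimates
the mode after normalization and fails the volume when it deviates from
$\mu_{\mathrm{ref}}$ by more than $0.5\,\sigma_{\mathrm{ref}}$ (an inclusive
bound; the threshold is configuration since the underlying method describes
the failure mode qualitatively). Failed volumes are excluded downstream.

**Cohort normalization (PET).** Per training image, `n_stats` is the
brain-voxel intensity at the 99.9th percentile (linear interpolation between
order statistics — `quantile` type 7 — so oracles can match bit for bit);
every volume is divided by the maximum `n_stats` over the *training* cohort.
The percentile rather than the maximum avoids single-voxel outliers driving
the scale. Values above the divisor in new images are retained unclipped —
the 0–1 range is a training-cohort-level property — and such volumes are
counted in the returned stats.

# Sub-score selection

The 13 items are min-max scaled so the classifier weighs them on equal
footing. Subjects are split 80:20 *first*, then each side is balanced by
randomly down-sampling its majority class (the alternative reading — balance
before splitting — risks leaking balance information across the split, so we
split first). A random forest is grid-searched (trees {100, 300}, minimum
node size {1, 5}, maximum leaf count {unbounded, 256}, selected by
out-of-bag error — OOB selection avoids a further inner split at these
sample sizes); impurity (Gini) importances are normalized to sum to one, and
the top-k items (default k = 4) become the regression targets.

# The 3D CNN

The regressor is a VGG-style 3D backbone of four convolutional groups with
2/2/3/3 layers — 10 convolutions of 3×3×3, each with batch normalization
before the ReLU — and a kernel-2 max pooling closing each group, so the
spatial extent halves four times. The two 3-layer groups are residual: the
outputs of their first and second layers are summed before the third layer
(elementwise, since channel counts match within a group). After the fourth
group the tensor is flattened — for the full-scale plan (channels
16/32/64/128, input 112³) that is 7³ × 128 = 43,904 features — into two
1024-unit (desk: 64-unit) tanh layers, and a per-task output head
$\sigma_\eta(x) = 1/(1+e^{-\eta x})$ whose sharpness $\eta$ is a single
trainable parameter shared across tasks, initialized at 1. Targets are
min-max scaled to [0, 1] (forced by the sigmoid head); predictions are
mapped back to raw score units for all reporting.

Training minimizes the mean over tasks of per-task MSE with Adam under a
cosine-annealing schedule
$\mathrm{lr}(t) = \mathrm{lr}_{\min} + \tfrac12(\mathrm{lr}_{\max} -
\mathrm{lr}_{\min})(1 + \cos(\pi t/T))$, $t$ the epoch index modulo the cycle
length $T$, restarting at $\mathrm{lr}_{\max}$ each cycle. The full-scale
configuration anneals between 0.01 and 0.0001 in 10-epoch cycles. The desk
configuration uses a *single* cycle with peak 0.001: a 200-subject cohort
yields only ~20 Adam steps per epoch, and at peak 0.01 the network reliably
collapses to predicting the per-task means (prediction variance shrinks
monotonically to zero) — a failure mode we verified against finite-difference
gradient checks to rule out an implementation cause. Batch size is 8. One
checkpoint (weights, batch-norm running statistics, test MSE) is recorded per
epoch; the 5–7 checkpoints with the lowest test-set MSE (ties broken toward
earlier epochs) form the ensemble, whose prediction is the arithmetic mean of
member outputs in scaled units. Fewer than 5 checkpoints are kept in full,
with a warning.

The network itself is implemented in single-precision C++
(RcppArmadillo): zero-padded 3×3×3 convolution as im2col + GEMM
(materialized per z-slab so peak memory stays bounded on 112³ inputs),
fused batch-norm/ReLU passes, and Adam. The backward pass is validated by
central-difference gradient checks on every parameter class, and the
convolution against a direct triple-loop reference.

Mentioned-but-unspecified architectural decorations of VGG-style models
(e.g. inception-type units) are deliberately not implemented; the
architecture is exactly the one described above.

# Evaluation and the ITV benchmark

Per task: MAE = mean |y_true − y_pred| and R² = 1 − SS_res/SS_tot, both on
raw score scales. The clinical yardstick is the inter-test variability: for
entry $i$, $\mathrm{ITV}_i = \max_j q_{ij} - \min_j q_{ij}$ over the
participant's visits dated within ±91 days of entry $i$ (inclusive; "±3
months" is ambiguous across month lengths, so days are used). Entries whose
window contains only themselves are excluded from the mean ITV by default —
counting their zero ranges would deflate the benchmark — with a flag to
restore the inclusive reading. A one-tailed Welch two-sample t-test (the
variance assumption is left free since the two samples are of different
kinds) asks whether mean absolute error exceeds mean ITV; "n.s." means the
model's errors are statistically within the score's natural fluctuation.

# Occlusion importance and its null

Region importance for region $i$ is $|\Delta \mathrm{MAE}_i| /
\mathrm{MAE}$: the relative change in ensemble MAE after setting region $i$'s
voxels to the fill value in every input. Fill = 0, the background value in
normalized units (zero-filling matches the occlusion literature; mean- or
noise-filling are alternatives a fork could explore — scores are only
comparable at a fixed fill, which is recorded in the table's metadata).
Importance is computed on the test split (the leakage-safe choice; a flag
admits the full cohort). Each region is occluded once and its predictions
reused across tasks and diagnosis sub-groups, which makes the CN/MCI/AD
sub-group tables cheap.

Attribution quality tracks fit quality. Because the four modelled sub-scores
share a severity component, an *underfit* network predicts every task from
whichever informative regions it found first, and occluding one task's region
then perturbs all tasks — the importance profile smears across the
informative regions. As the fit approaches the optimum (each task's score is
recoverable nearly noise-free from its own region, so the optimal predictor
has no use for the others), importance concentrates on the true region. This
is why the desk training budget (15 epochs) is set where the fit is good,
not merely where the loss first drops, and it is a caution for real data:
occlusion maps of underfit models are systematically diffuse.

The permutation null: predictions (baseline and per-region occluded) are
fixed, the subject-to-score assignment is permuted, and the maximum
importance over regions × tasks is recorded per permutation. On a cohort with
no planted effects the observed maximum should not exceed this spread; this
is a max-statistic test, so its false-alarm rate under exchangeability is
about $1/(B+1)$ per run.

Spearman correlations between per-task importance profiles use average ranks
for ties, exact p-values where the standard test provides them (small,
tie-free vectors) and the asymptotic approximation otherwise, with
Benjamini–Hochberg adjustment across the task pairs.

# Diagnostic extension

Each ensemble member's FC2 activations (the penultimate layer) are features
for three classifiers: logistic regression with a ridge penalty (glmnet,
`alpha = 0`, penalty equivalent to unit L2 strength, i.e. lambda = 1/n),
k-nearest neighbours (k = 5), and a random forest (200 trees). Per member ×
classifier, AUROC is computed on the held-out embeddings; the final label is
a hard majority vote over all member × classifier predictions, ties resolved
toward AD and flagged. Voting over member × classifier pairs (rather than
pooling embeddings across members first) keeps each member's feature space
intact; the pooled alternative is noted as an option. k, the penalty, and the
vote variant are all unstated in the underlying method and are exposed as
configuration.

# Problem sizes, tolerances, degenerate inputs

* **Desk preset** (package defaults): 32³ volumes, 8 atlas regions, 200
  subjects, channels 4/8/16/32, FC width 64, 15 epochs, batch 8. Chosen so a
  full pipeline run takes minutes on one CPU while leaving the planted
  signal recoverable; the validation suite runs five seeds of it.
* **Full preset**: 112³, 56 regions, channels 16/32/64/128, FC 1024 — the
  real-cohort configuration; only its shape contract (forward-pass trace) is
  exercised routinely.
* Oracle equivalences are asserted at 1e-10 (occlusion vs brute force) and
  1e-12 (hand-computed statistics); stochastic recovery criteria at the
  documented seed counts (e.g. planted-region top-2 rank in ≥4 of 5 seeds).
* Degenerate inputs fail loudly: flat images in NAWM estimation, zero stripe
  spread, non-positive PET divisors, zero-variance truths in R², zero
  baseline MAE in occlusion importance, single-class labels in
  classification, unparseable dates in ITV.
* Seeding: every stochastic function takes a seed and restores the caller's
  RNG state; the pipeline fans a global seed out to per-stage seeds
  (`seed + 1000 × stage index`) so stages are independently reproducible.
  Training is bit-reproducible for a fixed seed, machine and BLAS.

# Known limitations

* The synthetic generator's linear, region-additive signal is far easier
  than real morphometry; accuracy numbers on it say nothing about real-data
  accuracy.
* Training on one CPU at desk scale is the design point; the C++ core is
  single-threaded (BLAS aside) and full-scale training would require a GPU
  port.
* White-stripe assumes a detectable high-intensity tissue mode; heavily
  pathological or non-T1-like intensity histograms can mislead the peak
  picker — which is exactly what the QC stage is for.
* The ITV benchmark treats all within-window visits as exchangeable repeat
  measurements; real cognitive drift inside the window inflates ITV slightly.
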