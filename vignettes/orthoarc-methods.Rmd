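---
title: "Classifying and archiving orthodontic image series: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and archiving orthodontic image series: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`orthoarc` sorts the standard fourteen-image orthodontic record into its
categories and audits each patient's case for duplicated or missing images.
This vignette explains the models the package implements, the parameters
that matter, the numerical choices behind them, and what the synthetic test
cohorts do and do not establish about behaviour on clinical data.

## The pipeline

An incoming image takes one of two routes, decided by its channel count:

* **Grayscale images** (single-channel, or three identical channels —
  common when radiographs are exported as RGB) are radiographs. They are
  classified by aspect ratio alone: lateral cephalograms print near 1.2:1
  (width:height), panoramic radiographs near 2:1, and the decision
  threshold is the midpoint, 1.6 (configurable through `aspect_rule()`).
  The threshold is assigned to the panoramic side so the rule is monotone
  in the ratio. Portrait grayscale inputs (ratio below 1) are legal but
  unexpected; they raise a warning and take the nearest prototype. This
  rule is appropriate exactly when the two radiograph formats differ
  clearly in aspect ratio; archives whose cephalograms and panoramics are
  cropped to similar shapes would need a learned classifier instead, which
  is outside this package's scope.
* **Colour photographs** are resized to 450×300 or 300×450 by direct
  bilinear resampling (no padding; squares count as landscape; the resize
  is idempotent). A face detector then proposes a crop. Detection is a
  *contract* — any function mapping an image to scored boxes — because
  production deployments will want a trained detector; the built-in default
  (`detector_brightblob()`) thresholds luminance halfway between the image
  extremes and returns the largest bright connected component, which is
  reliable on the synthetic fixtures and serves as a reference
  implementation of the contract. When nothing is detected the full
  standardised image proceeds to classification, so detection failures
  degrade accuracy rather than dropping images.

"Transposition" of sideways-captured intraoral photographs is implemented
as an optional orientation normalisation inside `standardize_image()`
(`force_landscape`): a portrait image is rotated to landscape before the
resize. The workflow definition leaves the operation underspecified, so it
is off by default and exposed as a configuration flag.

## The network and its DeepID features

The classifier follows the DeepID recipe: train a small ConvNet with a
softmax head, then discard the head and use a late-layer embedding with a
separate verification model. The pinned architecture is

| stage | operation | output channels |
|---|---|---|
| conv1 | 7×7, stride 2, pad 3, ReLU | 16 |
| pool → unit2 | 2×2 max-pool; 3×3 conv + 1×1 projection shortcut, ReLU after the sum | 32 |
| pool → unit3 | same | 48 |
| pool → unit4 | same | 64 |
| pool → unit5 | same | 80 |
| conv6 | 3×3, ReLU | 64 |
| conv7 | 3×3, ReLU | 32 |
| head (training only) | linear 96 → 12 | — |

The DeepID feature is the concatenation of the globally average-pooled
conv6 and conv7 maps (64 + 32 = 96 values) — concatenation rather than
addition, matching the original DeepID design of drawing features from two
depths. Global average pooling makes the feature dimension independent of
input size; any RGB input with both sides ≥ 64 px is accepted.

Design choices worth stating explicitly:

* **Channel widths** (16, 32, 48, 64, 80, 64, 32) were chosen so the total
  trainable parameter count, including the 12-way head and all biases, is
  170,988 — i.e. 0.17 M, the architecture's one hard quantitative
  constraint. `build_network()` refuses any spec whose closed-form count
  leaves \[165k, 175k\], and `param_count()` asserts the instantiated
  arrays agree with the closed-form sum.
* **Residual units** are a single 3×3 convolution plus a 1×1 projection
  shortcut (identity when widths match), the minimal reading of "a residual
  shortcut after each of the four middle layers". Richer block interiors
  are possible but unconstrained by the parameter budget; the minimal form
  keeps the ledger exact.
* **No batch normalisation.** Plain biases keep the parameter count
  well-defined and training deterministic under a single seed.
* **Training** uses Adam (learning rate 0.001), batches of 50 and
  cross-entropy, with the checkpoint of the best validation accuracy
  returned — the reference recipe. The reference schedule is 100 epochs; on
  the separable synthetic cohorts the package trains at 150 px inputs for
  at most 30 epochs and stops early once validation accuracy reaches 1.0
  (`stop_at_val_acc`), which typically happens within 10 epochs. All
  randomness (initialisation, shuffling) flows from one integer seed, and
  the backward pass is hand-written and verified against numerical
  gradients (relative error ~1e−9 in the test suite).

Convolutions and pooling are implemented in C++ (im2col + GEMM via
RcppArmadillo); everything else — the training loop, Adam, the loss — is
plain R operating on batched arrays.

## The joint Bayesian verifier

A centred feature is modelled as x = μ + ε with identity component
μ ~ N(0, S_μ) shared within a category and residual ε ~ N(0, S_ε). Both
covariances are estimated by EM: the E-step computes, per category, the
Gaussian posterior of μ given the current covariances (in the Woodbury form
S_μ (m S_μ + S_ε)⁻¹ S_ε, which never inverts S_μ and so remains stable as
the identity variance collapses); the M-step averages the posterior second
moments. A ridge of 1e−6 · trace(S_ε)/d is added to S_ε each iteration;
iteration stops when the largest absolute entry change of both matrices
falls below 1e−6 or after 100 iterations. The marginal log-likelihood is
available (`jb_loglik()`, computed through the block eigenstructure of
I⊗S_ε + J⊗S_μ) and is non-decreasing across EM iterations in the test
suite.

Verification scores two features by the log-likelihood ratio of the
same-identity and different-identity hypotheses. With Σ = S_μ + S_ε and
[[Σ, S_μ], [S_μ, Σ]]⁻¹ = [[F+G, G], [G, F+G]], A = Σ⁻¹ − (F+G),

r(x₁, x₂) = ½(x₁ᵀA x₁ + x₂ᵀA x₂) − x₁ᵀG x₂ + c,

where c collects the determinant terms. The package includes c so that r is
the *exact* log-likelihood ratio (the scalar case then matches a
brute-force Gaussian density oracle to 1e−10); c is constant across pairs,
so classification — the argmax of r(x, mₖ) over the twelve per-category
gallery means mₖ, ties broken to the lowest category index — is unaffected.
The score matrix doubles as the input for one-vs-rest ROC analysis. The
verification model never sees the softmax head's probabilities; the head
exists only to train the embedding, and treating the joint-Bayes score as
the final classifier keeps the gallery extensible without retraining.

On parameter recovery: a test that regenerates features from the model
(200 identities × 10 samples, d = 8) cannot meaningfully compare the fitted
S_μ to its *nominal* value, because with 200 identities the realized
between-class covariance itself deviates from the nominal one by ~21% in
relative Frobenius norm — more than the recovery tolerance. The test suite
therefore compares the fitted S_μ to the realized covariance of the
simulated identity vectors (observed error ≤ 6%), which isolates the
algorithm's error from the luck of the draw, and the fitted S_ε to its
nominal value (≤ 10%, with 2,000 residual draws the nominal target is
estimable).

## Postprocessing and the archive

Occlusal photographs are captured through an intraoral mirror and arrive
left-right reversed; the pipeline mirror-flips every image *predicted*
maxillary or mandibular occlusal when writing the archive copy. The
integrity check counts, per patient, category slots with more than one
image (duplicates) and empty slots (missing); cohort totals satisfy the
conservation identity images = 14·patients + duplicates − missing by
construction, and the tests re-derive the totals by brute-force recounting.
"Duplicate" means more than one image assigned to one category slot —
near-duplicate pixel detection is deliberately out of scope, and choosing
which duplicate to keep is left to the human-review column of the archive
table. The archive table has one row per image (patient id, category,
predicted label, joint-Bayes confidence score, relative hyperlink,
duplicate flag, blank corrected-label column) followed by a per-patient
summary row naming missing and duplicated categories; the confidence column
records the joint-Bayes ratio of the winning class, not a calibrated
probability.

## The synthetic cohorts

The generator renders abstract geometric archetypes, not photorealistic
faces or dentitions: an ellipse "face" whose silhouette, hair-texture
orientation and mouth state encode the six extraoral poses (smiling opens
the jaw, lengthening the face, and exposes a bright tooth crescent); tilted
tooth-row bands, occlusal arches with an asymmetric marker, and an
offset-incisor close-up for the six intraoral views; and single-channel
textures at 1.2:1 / 2:1 for the radiographs. Every archetype pair differs
in at least 5% of template pixels, and the classes are separable by
translation-invariant convolutional statistics (the embedding is globally
pooled, so archetypes differ in local pattern and colour, never only in
position). Occlusal images are generated mirrored, radiographs
single-channel — so routing, flipping and integrity handling are all
exercised. Cohort structure is controlled either by explicit per-category
totals (surpluses become duplicates, deficits missing slots, distributed
deterministically from the seed) or by a defect model (a fraction of
patients receive ~2 defects each). One master seed drives per-image seeds,
so cohorts reproduce byte-identically.

Default study conditions: the desk-scale experiment trains on a 50-case
complete internal cohort (50 images per category, 600 photographs for the
network), holds out 8 images per class for model selection, renders at a
300 px base size, trains at 150 px inputs, and evaluates on a 100-patient
external cohort whose per-category totals follow the reference archive
(1,420 images; 60 surplus, 40 missing). Jitter levels (±10 px pose, ±8%
scale, ±0.04 colour, σ = 0.02 pixel noise) were chosen so that classes
remain cleanly separable while single-template pixel matching is no longer
perfect — the regime the reference pipeline assumes, where the network and
verifier have headroom to demonstrate correct wiring.

What passing tests show — and what they do not: the synthetic cohorts
validate the *mechanics* (routing, preprocessing, feature extraction,
EM fitting, gallery classification, flipping, integrity accounting,
archiving) and reproduce the reference accuracy under separable conditions.
They do not emulate photographic artefacts, exposure variation, patient
diversity or blur, so synthetic accuracy says nothing about clinical
accuracy; deploying on real archives requires a trained face detector
behind the detector contract and a retrained network. QC flags are taken
from the manifest (the reference workflow's blur review was manual);
automated blur scoring is out of scope.

## Degenerate inputs and tie-breaks

* Squares are landscape; the 1.6 aspect boundary classifies as panoramic;
  classification ties break to the lowest category index.
* An empty manifest yields an empty (header-only) archive table and a
  zero-finding report; unreadable images are excluded, recorded in
  `failures`, and the run continues.
* `max_epochs = 0` returns the freshly initialised network with an empty
  history; a single training class is an error, as is a joint-Bayes fit
  where every class is a singleton (S_ε unidentifiable).
* Category label order is fixed (frontal at rest first, panoramic
  radiograph last) for all arrays, reports and tie-breaks; splits sort
  paths within category before the seeded shuffle so results are identical
  across platforms.

## Known limitations

* The ratio rule fails on archives where the two radiograph formats share
  an aspect ratio; it is a rule, not a learner, by design.
* The built-in detector assumes the subject is the dominant bright region —
  true for the fixtures, not for clinical photographs.
* Joint-Bayes scores are uncalibrated log-likelihood ratios; do not read
  the confidence column as a probability.
* Training is CPU-bound R/C++ and sized for desk-scale experiments
  (hundreds of images), not for archives of tens of thousands of images.
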