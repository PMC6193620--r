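---
title: "Quantifying neonatal lung ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neonatal lung ultrasound: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In neonates with respiratory distress, lung ultrasound shows a progression
of patterns as aeration is lost: horizontal A-line reverberations in normal
lung, discrete vertical B lines as interstitial fluid accumulates,
coalescent B lines, and finally a bright, near-uniform subpleural field
with consolidations. Clinicians grade this progression per view on a 0–3
scale and sum the grades over eight standard views (four per side) into a
0–24 visual score. `neolus` implements both that visual scoring pathway and
a computer-assisted alternative: gray-scale and texture statistics of a
pleura-anchored region of interest (ROI), fed into a support vector
regressor of oxygenation, so the two approaches can be compared against
blood-gas reference standards — the oxygenation ratio PaO₂/FiO₂ and the
alveolar–arterial gradient A–a = PA − PaO₂ with
PA = FiO₂·(760 − 47) − PaCO₂/0.8 (mmHg).

## Region of interest

The ROI's upper limit follows a trace of the pleural surface (hand-drawn,
or for synthetic frames an automatic brightest-band heuristic smoothed by a
15-column moving median). The lateral sides are vertical lines through the
trace endpoints ("square angles"), and pixels run from one pixel below the
linearly interpolated trace down to a common depth. The depth is the
smallest integer reaching the target area — 50,000 or 100,000 pixels by
convention — and the surplus is trimmed from the deepest layer, rightmost
columns first, so the achieved area is *exactly* the target. Two
consequences matter for interpretation: the two standard areas built from
one trace are nested (the larger adds deeper rows only, so they differ
exactly in the deeper lung contribution), and no ROI pixel ever sits at or
above the traced pleural row. The trace itself is placed at the top edge of
the pleural band so the bright pleural pixels fall inside the ROI.

## First-order and texture features

First-order analysis is a 256-bin histogram, the arithmetic mean and the
population variance (divide by *n*; at ROI sizes of 50,000 pixels the
sample/population distinction is negligible, but tests need one pinned
definition). The eight per-frame ROI means of a patient are pooled into one
gray-scale mean intensity score.

Second-order analysis uses the gray-level co-occurrence matrix (GLCM):
P<sub>ij</sub> is the normalized count of ordered pixel pairs (p, p+offset)
with quantized gray levels (i, j), both pixels inside the ROI. The pipeline
uses 2-pixel offsets along the horizontal (0, +2) and vertical (+2, 0)
directions. Twenty-two descriptors are computed per direction — ten
classical ones (entropy, homogeneity, dissimilarity, cluster shade and
prominence, autocorrelation, contrast, energy, variance, maximum
probability), seven defined on the distributions of the sum and absolute
difference of co-occurring levels (inverse difference, contrast, sum
average, sum and difference entropy, sum and difference variance), and five
correlation-based ones (two algebraically identical correlation forms, the
maximal correlation coefficient from the second eigenvalue of the
transition-like matrix Q, and the two information measures of correlation)
— giving a 44-dimensional per-frame vector, ordered horizontal-first with
groups 1, 2, 3 within each direction.

Numerical conventions, chosen so the pipeline never emits a non-finite
value and recorded per frame when they fire:

* gray levels are the quantized values 0..L−1 (`level = floor(gray·L/256)`);
  L defaults to 256 (native 8-bit, no re-quantization) and may be any
  divisor of 256 — oracle tests use L = 8;
* all entropies use the natural logarithm with 0·log 0 ≡ 0 (the base only
  rescales entropy features);
* the GLCM is ordered (not symmetrized): each pair is counted once;
* the variance feature uses μ = Σᵢⱼ i·P<sub>ij</sub>, the mean level of the
  first pixel of a pair under P;
* the sum variance uses the sum entropy inside its square, and the maximal
  correlation coefficient is the second eigenvalue itself (by modulus, real
  part), not its square root;
* zero marginal SD ⇒ both correlation forms are 0; fewer than two occupied
  levels ⇒ MCC = 0; a zero entropy denominator ⇒ IC1 = 0; a negative
  radicand in IC2 is clamped to 0.

The two deliberately duplicated formulas (contrast computed directly and
through the difference distribution; the two correlation forms) are kept as
separate code paths and their equality is asserted in tests — a cheap
internal consistency check on the whole marginal machinery.

## Severity model

The regressor is an RBF-kernel support vector machine trained at frame
level: every frame inherits its patient's index value as target, and a
patient's prediction is the mean over its frames — mirroring how the
first-order means are pooled. Validation is leave-one-patient-out: all
frames of the held-out patient are excluded from training, and feature
standardization is refitted inside every training fold, so no scaling
information leaks. Hyperparameters (all config-exposed): cost C = 1,
epsilon = 0.1 × SD of the training targets, gamma = 1/(p × mean feature
variance). The regression target is standardized inside the fit and
predictions back-transformed; this keeps C meaningful regardless of the
index's physical scale (PaO₂/FiO₂ spans hundreds of mmHg — an unscaled
epsilon-SVR with C = 1 cannot even span that range, since its output is
bounded by the summed coefficients).

For ROC analysis the continuous per-patient predictions are scored against
the dichotomized true index — PaO₂/FiO₂ < 200 mmHg or A–a > 150 mmHg as the
positive ("worse") class — with predictions of PaO₂/FiO₂ negated so that a
higher score always indicates the positive class. AUC uses the
Mann–Whitney pair-counting estimator with ties counted one half. Group
analyses restrict the 44 columns to one feature group (both directions);
the PCA sweep keeps the component fit strictly inside each training fold
for prediction, while the descriptive explained-variance curve is fitted
once on all standardized frames.

Two properties of leave-one-out machinery are worth knowing when reading
permutation controls: predictions under shuffled targets carry a small
O(1/n) *anti*-correlation with the held-out value (excluding a patient
shifts the training mean away from it), so null AUCs center slightly below
0.5 in small cohorts; and an RBF regressor cannot extrapolate beyond the
training target range, so the extreme patients of a cohort are predicted
conservatively. Tests account for both (larger null cohorts; recovery
checks with anchored extremes).

## Evaluation statistics

Spearman's rho uses average ranks for ties, a t-approximation p value, and
a 95% CI from the Fisher z transform with SE = 1/√(n−3) (the CI method is a
package choice; several are in use and none is canonical). Interobserver
agreement is unweighted Cohen's kappa over frame-level grade pairs (the
natural unit for "concordance between operators"); agreement on the
per-patient sums and a linear-weighted kappa are available as secondary
outputs. When both raters are constant and identical, kappa is defined
as 1.

## The synthetic cohort generator

No clinical images ship with the package; the generator is first-class,
tested code that emulates the *structure* of a neonatal study cohort so
that every downstream stage is exercised under realistic conditions:

* **Frames** (512×384 px, pleural line at row 48 — large enough that a
  100,000-pixel ROI fits below the pleura): a bright pleural band plus
  grade-dependent subpleural content — A-lines at multiples of the pleural
  depth (grade 0), 4–8 well-spaced vertical streaks (grade 1), overlapping
  wide streaks on a raised background (grade 2), a bright field with darker
  consolidation blobs and a jittered, irregular pleural band (grade 3).
  Expected subpleural mean intensity is strictly increasing in grade by
  construction. Multiplicative speckle uses a Rayleigh amplitude normalized
  to unit mean, blended as 1 + σ(X−1) with σ = 0.3, so the expected image
  is the noiseless scene and σ = 0 is exactly noise-free.
* **Severity law**: each patient has a latent severity s ~ Uniform(0, 1);
  per-view grades are clip(round(3s + ε), 0, 3) with ε ~ N(0, 0.5);
  FiO₂ = 0.21 + 0.59s; PaO₂/FiO₂ = clip(400 − 280s + N(0, 40), 50, 500)
  mmHg; PaCO₂ ~ clip(N(45, 7), 25, 80) mmHg. The constants are chosen so a
  75-patient cohort lands near the demographics of a real neonatal
  intensive-care population (mean oxygenation ratio in the low-to-mid 200s)
  and the sign structure of the clinical correlations is recoverable; all
  are config-exposed.
* **Raters**: two simulated observers report the true grade with
  probability 1 − 0.05, otherwise an adjacent grade, independently per
  rater and frame.
* **Reproducibility**: one global seed drives a hierarchical
  per-patient/per-frame seed stream (multiplicative-congruential children
  modulo 2³¹ − 1), so any frame can be regenerated in isolation and a
  cohort is bit-identical across runs.

What the generator does *not* emulate — and therefore what passing tests do
not show about clinical data: probe geometry and attenuation, log
compression and gain settings, anatomical variability of the pleura, rib
shadows, or the actual gray-level statistics of the four grades (the
renderers are qualitative emulations of the published pattern
descriptions). Correlations on synthetic cohorts are cleaner than any
clinical cohort's; the package's cohort-level checks are therefore
qualitative (signs, ordering, informative AUCs), not reproductions of
clinical effect sizes.

## Problem sizes and runtime choices

The default study shape is 75 patients × 8 views = 600 frames. Cohort-level
tests and the acceptance script run this full size with the 50,000-pixel
ROI (texture extraction is the dominant cost, about 60–70 ms per frame and
direction at L = 256, most of it the 256×256 eigendecomposition behind the
maximal correlation coefficient); module-level tests use small frames and
small-L oracle images. The PCA plateau check uses constructed
latent-factor features rather than image-derived ones, which isolates the
sweep machinery from the renderers.

## Known limitations

* The automatic pleural trace is a brightest-band heuristic intended for
  synthetic frames; clinical images need hand traces (CSV polylines).
* DICOM support is deliberately minimal: single-frame uncompressed
  little-endian monochrome, which covers still-frame exports but not cine
  clips or compressed transfer syntaxes.
* The feature-group partition (10/7/5) follows the only size-consistent
  assignment of the 22 descriptors to the three published group
  descriptions; it is an inference, not a printed list.
* Whether per-frame or per-patient scores fed the published group AUCs is
  not stated; the package scores per patient, consistent with the
  leave-one-patient-out unit.
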