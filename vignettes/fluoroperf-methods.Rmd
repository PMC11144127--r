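---
title: "Models and methods in fluoroperf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fluoroperf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fluoroperf)
```

`fluoroperf` re-implements, at desk scale, a fluorescence-augmented
lesion-characterisation pipeline for ambiguous rectal polyps, plus the
multi-rater clinical-judgement statistics that such a classifier is
compared against. Every stage runs against a synthetic data generator
with exact ground truth, so the whole chain is testable without clinical
recordings. This vignette documents the models, the tunable parameters,
the numerical choices, and what a green test does and does not
establish.

## 1. The perfusion model

After an intravenous indocyanine green (ICG) bolus (0.25 mg/kg — carried
as metadata only; no pharmacokinetic compartment model is attempted),
tissue fluorescence in the near-infrared (NIR) channel rises and washes
out. The simulator uses the standard bolus-transit *gamma-variate*
family:

$$I(t) = \mathrm{baseline} + A \cdot \frac{g(t - t_0)}{g_{\max}}
  + \varepsilon(t), \qquad g(u) = u^{\alpha} e^{-u/\beta}\ (u > 0),$$

with $\varepsilon \sim N(0, \sigma^2)$ i.i.d. per sample (per pixel per
frame in video rendering) and clipping at 0. The peak scaling makes $A$
the peak gain in intensity units. Useful closed forms, used as oracles
throughout the tests:

* curve maximum at $t_0 + \alpha\beta$;
* intensity-weighted mean time (centre of mass) $t_0 + (\alpha+1)\beta$
  (the weight is a $\mathrm{Gamma}(\alpha+1, \beta)$ density);
* intensity-weighted skewness $2/\sqrt{\alpha+1}$.

Per-class defaults (`default_kinetics()`): malignant tissue arrives
earlier ($t_0$ 6 s vs 10 s benign), peaks earlier ($\alpha\beta$ 6 s vs
12 s) and washes out faster; normal mucosa sits between with lower
amplitude. These magnitudes are *simulator configuration chosen for test
separability*, not biological claims: the real tissue-specific kinetic
values are not published, only the direction (malignancy alters the
perfusion profile).

Gaussian rather than Poisson/photon noise is deliberate: it keeps every
downstream tolerance closed-form ($\sigma/\sqrt{n_\mathrm{px}}$ for a
region mean).

## 2. The synthetic scene

`scene_spec()` describes a static tissue scene filmed by a jittering
camera: 30 fps and ≥ 120 s by default, matching the acquisition protocol
of the targeted workflow. The white-light channel is a high-contrast
random texture (ideal for correlation tracking; real mucosal texture is
less friendly — see limitations), translated rigidly per frame by an
integer jitter series; the NIR channel holds each labelled region at its
class curve under the same jitter. Masks, displacement series and
generating curves are returned as exact ground truth. Whole-pixel
global translation only — no rotation, deformation, occlusion, lighting
change or photorealism; that is precisely the contract the tracker is
specified against.

The default frame size (64×64 px) is a memory/runtime compromise so the
full-duration default bundle (3600 frames per channel) renders in
seconds; nothing in the pipeline depends on absolute frame size beyond
ROI area ≥ 25 px.

Interchange formats are deliberately boring: multi-page 16-bit
grayscale TIFF per channel (written by a built-in baseline codec, since
no TIFF package is available in the target environment; its output is
cross-checked against `tifffile` in the IO tests), 8-bit label TIFF
masks, JSON ROI boxes (0-based, half-open, row/col), CSV curves/tables
and a YAML manifest carrying every parameter and seed, so a bundle is
self-describing and reproducible from its manifest alone.

## 3. Tracking and curve extraction

`track_roi()` is a frame-0 template tracker: within a ±15 px search
window it maximises the normalized cross-correlation (NCC) between the
ROI template and each candidate patch. NCC of a zero-variance patch is
defined as 0, which automatically flags degenerate frames (e.g. an
all-black dropout) below the 0.5 validity threshold. Optional 1-D
parabolic interpolation around the peak gives sub-pixel estimates
(off by default; the synthetic jitter is integer). No template update is
performed by default — scenes are static by construction, and template
drift is the classic failure mode of updating trackers.

`extract_curve()` averages the NIR channel over the ROI footprint
displaced by the (rounded) estimated track. Invalid frames are filled
by linear interpolation in time between the nearest valid neighbours
(endpoints hold), or dropped when requested; how the original clinical
workflow handled tracking dropouts is not documented, so the policy is
explicit and configurable. A displaced footprint leaving the frame is
an error naming the first offending frame, not a silent crop.

## 4. Milestones

`preprocess_curve()` smooths with a centred 15-frame (0.5 s) moving
average, takes the baseline as the mean of the first 2 s (which must end
before the detected onset — the first sustained 0.5 s excursion above
0.05 of the normalized range), and rescales so the smoothed curve peaks
at 1. A flat or decaying curve is a hard "no perfusion event" error.

`extract_milestones()` then computes, on the normalized curve:

| milestone | definition | units |
|---|---|---|
| `t_peak` | argmax time of the smoothed curve | s |
| `upslope` | least-squares slope between the 10% and 90% crossings of the rising limb | 1/s |
| `downslope` | least-squares slope from the peak to ≤ 60 s after it | 1/s |
| `com` | intensity-weighted mean time, weights clipped at 0 | s |
| `skew` | intensity-weighted third standardized moment about `com` | — |

Slopes are computed on the normalized curve, making them amplitude-free;
all milestones are invariant to multiplying raw intensities by any
$c > 0$, and `t_peak`/`com` shift exactly with a time shift.

Two numerical choices deserve their own paragraphs.

**Moment window.** The weighted moments use the *whole* recording with
negative normalized values clipped at 0, not a window starting at the
detected onset. Truncating at the 0.05 onset measurably biases the
third moment (up to ~0.015 against the closed form on noise-free
draws, outside the 0.01 oracle tolerance), because the gamma tail below
threshold carries real cubic mass. With clipping, the noise-free
closed-form error is ~0.0025 (residual smoothing effect) for `com` and
`skew` across the tested parameter range.

**Skew under noise.** Clipping makes baseline noise contribute a small
positive weight everywhere; over a long quiet tail the cubic moment
amplifies it (measured: skew inflated by ~0.3 at per-pixel noise sd 5
over 120 s at 64×64-region SNR). Removing the clip makes the estimator
unbiased but wildly variable, and windowing reintroduces the truncation
bias above. The clipped full-window definition is kept because the bias
is common to all tissue classes (the classifier standardizes each
feature per training fold, so a shared offset is harmless) and the
closed-form fidelity requirement binds only in the noise-free regime.
Consequence: absolute skew values from noisy recordings should not be
interpreted against the $2/\sqrt{\alpha+1}$ closed form.

`relative_features()` appends lesion-minus-normal deltas for all five
milestones. Whether the original classifier used absolute milestones,
deltas, or both is not documented; the feature table carries both and
the classifier configuration chooses (default: both).

## 5. Classification

The "optimizable ensemble" is realized as a seeded search over two
tree-ensemble families — bagged trees and gradient-boosted trees — with
the grid trees ∈ {50, 100, 200}, depth ∈ {2, 4, 8}, and learning rate
∈ {0.05, 0.1, 0.3} (boosted only). The trees themselves are grown
in-package (no tree library exists in the target environment):
greedy binary splits by variance reduction — equivalent to Gini for 0/1
responses — with Newton-step leaf values for the logistic-loss boosting.

Scoring is mean accuracy over **patient-grouped** 5-fold
cross-validation: all ROIs of a patient share a fold, since ROIs within
a patient are correlated and row-level folds would leak. Per-feature
standardization is refit on each training fold. The winner is refit on
all data; the model archive (JSON) stores trees, hyperparameters,
scaler, schema, seed and the CV report.

ROI calls aggregate to a patient call by the "any cancer ROI ⇒ cancer"
rule by default (the alternative, "majority" with ties to cancer, is a
config switch). The "any" default is the reading consistent with a
screening-type operating point — maximal sensitivity at the cost of
false positives — which matches the published pattern (100% sensitivity,
2 false-positive patients). Decision threshold 0.5; report percentages
are rounded half-away-from-zero to integers, raw values retained.

The published clinical accuracies (91.7% CV on the 32-polyp training
set, 87% ROI / 86% patient on 14 unseen lesions) require the trial
recordings, which are not public: they are *mechanism targets only*
here. What the tests establish instead: ≥ 95% grouped-CV accuracy on a
synthetic dataset whose class centres sit several pooled SDs apart
(with an independent nearest-centroid oracle agreeing), chance-level
accuracy under label permutation, and no improvement with increasing
sensor noise.

## 6. Rater statistics

For $N$ items rated by $n$ raters into categories with counts $n_{ij}$:

$$P_i = \frac{\sum_j n_{ij}^2 - n}{n(n-1)},\quad
\bar P = \tfrac1N \sum_i P_i,\quad
p_j = \frac{\sum_i n_{ij}}{Nn},\quad
P_e = \sum_j p_j^2,\quad
\kappa = \frac{\bar P - P_e}{1 - P_e},$$

with the large-sample standard error

$$SE^2 = \frac{2}{Nn(n-1)}\cdot
\frac{P_e - (2n-3)P_e^2 + 2(n-2)\sum_j p_j^3}{(1-P_e)^2}$$

and a 95% CI of $\kappa \pm 1.96\,SE$. This exact formulation is frozen
because, applied to the packaged vote-count reconstruction (majority
share × 32, rounded; the even polyp 16/16), it reproduces the published
panel result to all printed digits (κ = 0.261, CI 0.237–0.285,
band "fair"). Agreement bands: < 0.20 poor, 0.21–0.40 fair, 0.41–0.60
moderate, 0.61–0.80 good, 0.81–1.0 very good; the conventional table
leaves gaps (e.g. 0.205), which map to the lower band with a warning.

Other estimators: Likert 1–5 frequency tables with means reported to
2 decimals (half-away-from-zero, as SPSS prints — banker's rounding
would print 3.12 for 3.125 where the published table has 3.13);
majority decisions with exact 50/50 splits flagged "even" and counted
as *not* correct; per-rater accuracy/sensitivity/specificity (cancer
positive) aggregated to grade/interest groups as means with min–max
ranges; Spearman correlation as Pearson on average ranks with the
$t_{n-2}$ approximation; signed size error
$(\text{estimate}-\text{actual})/\text{actual} \times 100$.

Two published figures are deliberately *not* asserted. The overall mean
accuracy (49%) needs per-rater raw responses (published marginals give a
pooled 46.4%, so the per-rater averaging basis cannot be reconstructed).
The 20%/15% mean size errors recompute from the published per-polyp
means as 21.4%/15.6%; the averaging basis (per rater vs per polyp mean)
is unstated, so both recomputed values are reported and flagged rather
than asserted. Likewise the published Spearman coefficients (−0.01,
0.152) need per-answer raw data; the mechanism is implemented and
oracle-tested, the values are not targeted.

## 7. The rater simulator

A Rasch-style model: rater $r$ answers item $i$ correctly with
probability $\mathrm{logistic}(\mathrm{skill}_r -
\mathrm{difficulty}_i)$, independently across cells; confidence is the
(noisy, sd 1) margin cut at {−2, −0.5, 0.5, 2} into Likert 1–5, so
confidence correlates with ability without being deterministic. This is
a stand-in for survey raters, built for controllability: saturation
(margin +10 ⇒ 100% accuracy), chance (margin 0 ⇒ Fleiss κ with mean 0
over replicates), and binomial convergence of cell accuracy are all
exact test targets. It does not model answer correlation across items
within a rater beyond the skill term, nor rater-specific bias toward a
category.

## 8. Determinism and seeds

Every stochastic operation takes a seed and restores the caller's RNG
state. The pipeline's single seed fans out to per-stage seeds through a
fixed stage-name hash, so any stage can be re-run in isolation with
identical output; two runs of the same configuration produce
byte-identical report JSON (timestamps are excluded from reports for
exactly this reason).

## 9. Scaling of the test suite

The acquisition default (120 s × 30 fps) is exercised once (bundle
round-trip and frame count); everything else runs on 6–12 s scenes with
proportionally faster kinetics and on reduced classifier search grids,
purely for runtime. Green tests therefore establish correctness of the
mechanisms at desk scale — oracle agreement, invariances, exact
reproduction of published table arithmetic — not clinical performance,
video realism, or robustness to non-rigid motion.

## 10. Known limitations

* Tracker: global integer translation only; real endoscopy has
  deformation, specular highlights, scope withdrawal and occlusion.
* Random-noise texture is the best case for NCC; textureless mucosa
  would degrade tracking far below the ≤ 1 px MAE seen here.
* Skew from noisy recordings carries the clipping bias discussed above.
* The tree ensembles are small-data implementations (greedy splits, no
  pruning, no missing-value handling); feature tables are expected to
  be complete.
* The rater-table reconstruction recovers only per-polyp marginals;
  rater-level longitudinal structure is synthetic.
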