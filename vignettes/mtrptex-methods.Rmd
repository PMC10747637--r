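---
title: "Texture-feature discrimination of myofascial trigger points: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-feature discrimination of myofascial trigger points: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Myofascial trigger points (MTrPs) are hyperirritable nodules in taut bands
of skeletal muscle; *active* MTrPs are spontaneously painful, *latent* ones
painful only on palpation.  In B-mode ultrasound they present as large
hypoechoic (dark) contracture knots inside the muscle band between the
superior and inferior fascia, sometimes containing small hyperechoic
"speckle" dots.  Manual palpation is unreliable, which motivates
quantitative texture analysis of the ultrasound image itself.

`mtrptex` implements a complete texture pipeline for the three-class
problem (active MTrP / latent MTrP / healthy): four feature-extraction
approaches, leave-one-site-out (LOSO) evaluation of seven classifier
families, majority-vote ensembling, single-feature and
leave-one-feature-out importance analyses, and one-way ANOVA group
comparisons.  Because clinical images of this kind are generally not
redistributable, the package ships a synthetic cohort generator with full
ground truth; every statistical claim the test suite makes is made against
that generator.

## The synthetic cohort generator

`generate_cohort()` emulates the acquisition design the analysis assumes:
90 muscle sites (30 per group; one site = one side of one participant's
upper trapezius), a 10 s sweep at 30 frames/s per site (300 frames), of
which 4 frames spanning the sweep are retained, and a rectangular muscle
ROI between two bright fascia bands.

The image model is the standard fully-developed-speckle assumption:

* a smooth background `B(r) = B0 (1 - a r/H)` decaying with depth
  (`B0 = 100` on the 8-bit scale, attenuation `a = 0.35`),
* multiplied by low-contrast oriented fiber striations (sinusoid, relative
  amplitude 0.06, period 10–14 px, near-horizontal),
* multiplied, inside a lesion, by `1 - d` over an ellipse (the hypoechoic
  knot) and by Gaussian bumps of gain 1.8 at up to 6 interior points (the
  hyperechoic dots),
* plus additive Gaussian-profile fascia bands,
* all multiplied by i.i.d. unit-mean Rayleigh speckle and quantized to
  0..255.

The echogenicity drop `d` is the effect-size dial: defaults are `d = 0.5`
for active and `d = 0.25` for latent sites, and `d = 0` (no lesion) for
healthy sites, so the expected ROI intensity orders
healthy > latent > active.  These two values are free parameters of the
phantom, not claims about physiology: no published quantification of the
sonographic difference between active and latent MTrPs exists, so the
defaults are chosen once to produce a clearly recoverable effect and are
exercised as such by the tests.  Setting both drops to zero
(`null_cohort_config()`) makes the three groups exchangeable — the null
configuration used for calibration checks.

The lesion ellipse spans about 60&nbsp;% of the inter-fascial band height
and 30&nbsp;% of the frame width (a "large" contracture knot), and its
center drifts laterally by `image_width / frames_per_site` pixels per
frame, wrapping at the frame edge, so the 4 selected frames always view
different sections of the knot — emulating the ~1 cm/s probe sweep along
the muscle while keeping the lesion in view, as a sonographer selecting
frames would.  Frame selection itself is deterministic even spacing with
endpoints (`select_frames()`): manual frame selection cannot be emulated,
and a deterministic rule keeps runs reproducible.

Each site draws its latent parameters (gain jitter, fascia positions,
striation phase, lesion placement) from a seed derived from the cohort
seed, and each frame draws its speckle from a seed derived from the site
seed, so any subset of frames renders bit-identically to the full sweep
and `(config, seed)` determines every pixel.

What the phantom does **not** model: wave propagation, probe pressure and
anisotropy artifacts, acoustic shadowing, inter-operator gain variation,
and any real histological texture of muscle.  Passing tests on this
phantom therefore demonstrate that the pipeline recovers a known
echogenicity effect under speckle — not that it would classify clinical
images at any particular accuracy.

## The four feature approaches

All four approaches reduce to the same seven statistics
(`stats7()`), applied to different matrices:

| approach | input matrix to `stats7()` | features |
|---|---|---|
| `bmode` | the ROI intensity matrix | 7 |
| `lbp` | the LBP code image of the ROI | 7 |
| `gabor` | each of 40 Gabor energy responses | 280 |
| `segl` | each of 8 direction-indexed GLCM edge images | 56 |

**Local binary patterns.** Each pixel's 8 neighbors (3×3 neighborhood,
radius 1) are thresholded against the center, `s(x) = 1` iff `x ≥ 0`, and
summed with weights `2^p`, `p = 0..7`, enumerated clockwise from the
top-left neighbor.  Borders are replicate-padded before coding.  Any fixed
enumeration gives a bijection of codes; the clockwise-from-top-left choice
is declared and frozen in the tests.  Codes depend only on intensity
differences, so LBP features are invariant under monotone intensity remaps
— the property that makes them attractive for gain-variable B-mode data.

**Gabor bank.** 40 complex kernels, 5 scales × 8 orientations
(0°, 45°, …, 315°): a Gaussian envelope modulated by a complex plane wave
with rotated coordinates `x' = x sinθ + y cosθ`, `y' = −x cosθ + y sinθ`.
Frequencies follow the geometric ladder `f_s = 0.25/√2^s` cycles/pixel and
the envelope scales with wavelength, `σ = 0.56/f` — the convention of the
widely used Gabor feature-extraction implementations.  Kernels are
truncated at 3σ.  Responses are the complex filter magnitude followed by a
5×5 local mean ("energy") window.  Orientations 180° apart are complex
conjugates and give identical magnitudes; all 8 are kept so the bank and
the feature layout have the declared 40/280 shape.

**SEGL.** The composite statistical/edge/GLCM/LBP chain, in the order:
LBP image → per-direction GLCM (8 compass directions, offset 1 pixel,
256 levels, unsymmetrized, normalized) → the GLCM rendered as an intensity
matrix (min–max rescaled to 0..255, necessary because GLCM entries are
probabilities) → Canny edges → the seven statistics of the binary edge
matrix.  This ordering is the one that yields exactly 8 direction-indexed
images and hence 8 × 7 = 56 features; the alternative reading (edges on
the LBP image, then GLCMs of the edge image) is available as
`variant = "lbp_edges"`.  A direction with no edge pixels falls back to
the statistics of the uniform matrix, with a warning that the run summary
counts.

**The seven statistics.** With `P` the sum-normalized input matrix and
`i, j` zero-based row/column indices:

* entropy `−Σ P ln P` (with `0 ln 0 = 0`), contrast `Σ P (i−j)²`,
  correlation `Σ P (i−μ)(j−μ)/σ²`, homogeneity `Σ P/(1+(i−j)²)`,
  energy `Σ P²`, mean `Σ i P`, variance `Σ P (i−μ)²`,

where `μ` and `σ²` are the mean and population variance of the entries of
`P`, and correlation is defined as 0 when `σ² = 0`.  Applying the formulas
literally to the sum-normalized matrix is the one reading that covers all
four approaches uniformly (image, code image, response image, or edge
matrix); it is deliberately frozen even where a GLCM-specific reading
would differ.

An important consequence of the normalization: overall image brightness
cancels.  On the B-mode approach, "mean" is the row centroid of
normalized image mass and "variance" its spread — *location* statistics —
while the statistics that respond systematically to a hypoechoic knot of
random position are **entropy, energy, and correlation** (the knot
reshapes the distribution of normalized mass wherever it sits).  The power
property test asserts ≥95&nbsp;% ANOVA rejection on those three
echogenicity-responsive statistics at the default effect sizes; the
centroid-type statistics have no systematic group effect in this phantom
by symmetry of lesion placement.

## Evaluation design

**LOSO.** One fold per site: all 4 images of the held-out site are the
test set, the other sites' images the training set (90 sites → folds of
356/4 images).  Features are z-scored with training-fold statistics only;
zero-variance features are dropped with a warning.  Standardization is a
package decision (not part of the emulated protocol): kNN, SVM, LR and the
NN are scale-sensitive and the feature magnitudes span many orders.

**Classifier families and frozen parameter sheet.** The hyperparameter
grids are: kNN `k ∈ {3,5,7}`; decision tree and random forest split
criterion `∈ {gini, entropy, log_loss}`; logistic regression and SVM
`C ∈ {0.1, 1, 10}`; Gaussian naive Bayes
`var_smoothing ∈ {1, 10⁻⁵, 10⁻⁹}`; the NN has no grid.  So behavior does
not drift with library versions, every remaining default is pinned:

* kNN: `class::knn`, Euclidean.
* DT: `rpart`, `cp = 0`, `minsplit = 4`, `minbucket = 2` (deep trees);
  `entropy` and `log_loss` are the same splitting criterion and both map
  to rpart's `"information"`.
* RF: `randomForest`, 100 trees; Gini splitting only — the `entropy` /
  `log_loss` grid values run with Gini splitting (the available
  implementation), keeping the declared grid shape.
* LR: `glmnet` multinomial ridge with `λ = 1/(C·n)`, the exact
  correspondence to a `C`-parameterized L2 objective.
* NB: Gaussian likelihoods with per-class variances inflated by
  `var_smoothing × max_j Var(x_j)` of the pooled training fold; classes
  absent from a training fold are excluded from prediction.
* SVM: `e1071::svm`, RBF kernel, `γ = 1/p` on standardized features.
* NN: input → dense 512 (ReLU) → dropout 0.5 → dense 3 (softmax), Adam
  (lr 10⁻³, batch 32), ≤250 epochs, early stopping on validation loss
  (patience 7, best weights restored), learning-rate reduction on plateau
  (factor 0.1, patience 3, floor 10⁻⁵).  The validation split is at the
  *site* level, 75/25 (89 sites → 67/22, i.e. 268/88 images), preventing
  images of one site from straddling the split.

One master seed fans out deterministically per fold, so identical inputs
give identical predictions.

**Metrics.** The six metrics are micro-averaged over the three classes:
per-class TP/FP/FN/TN are pooled before computing sensitivity,
specificity, PPV, NPV; F1 is the harmonic mean of micro PPV and micro
sensitivity; accuracy is reported as a percentage.  With balanced classes
micro-averaging implies two arithmetic identities — sensitivity equals
accuracy/100 and specificity equals (1 + accuracy/100)/2 — which the test
suite verifies both on constructed confusion matrices and as exact
properties of `classification_metrics()`.

**A LOSO caveat worth knowing.** Under LOSO with balanced groups, the
held-out site's class is always slightly *under*-represented in training
(29 of 89 sites).  A classifier with no usable signal that falls back to
training priors therefore predicts the held-out class *less* often than
chance — in the extreme (an underfit RBF SVM at `C = 0.1` on label-free
features) it never predicts the held-out class and scores near 0, far
below the nominal 1/3.  This is a property of the design, not a bug; the
null-calibration checks therefore run each technique at the
hyperparameter selected on a strong-effect cohort (the way the pipeline
itself operates after `grid_select()`), where all seven techniques sit
inside the 99&nbsp;% binomial band around 1/3.

**Ensemble and importance.** `grid_select()` picks, per technique, the
hyperparameter with the best mean accuracy across the evaluated
approaches (ties go to the first grid value).  The selected classifiers
vote per image; ties among vote counts break by the fixed group order
(A-MTrP < L-MTrP < healthy) and are counted, so voting is deterministic
and tie frequency reportable.  Importance analyses rebuild reduced
feature tables: one statistic across the four approaches (4 values per
image; the 40 Gabor and 8 SEGL instances are mean-aggregated), or all but
one statistic (24 values), and re-run the LOSO evaluation on them.

## Group-level ANOVA

`one_way_anova()` is the classic between/within decomposition with
`F = MS_between/MS_within` and p from `F(2, n−3)`; degenerate inputs
follow fixed conventions (all groups identical → F = 0, p = 1; zero
within-group variance with nonzero separation → F = ∞, p = 0).  The
summary table covers 7 statistics × 4 approaches with per-group means and
SDs, raw p values flagged at 0.05, and an informational Bonferroni
column (no correction is applied to the primary values).

The unit of analysis defaults to the *image* (120 per group with default
settings), with a *site* option that averages each site's 4 images.
Images within a site share the site's latent parameters, so image-level
observations are pseudo-replicated and anti-conservative whenever genuine
site-level variation exists; the calibration simulations therefore use
the site unit, which is the statistically defensible choice, while the
image unit is retained as the default presentation.

## Numerical choices

* Canny: Gaussian σ = 1, hysteresis thresholds 0.1/0.2 of the maximum
  gradient magnitude, Sobel gradients, 4-sector non-maximum suppression.
  At a symmetric two-pixel magnitude tie across an ideal step edge the
  pixel on the forward side of the (sign-folded) gradient direction is
  kept, with a 10⁻⁹-relative tolerance absorbing floating-point
  asymmetry, so step edges give one-pixel lines and the edge set is
  exactly invariant under intensity inversion.
* Gabor filtering uses FFT cross-correlation with replicate padding;
  composite FFT sizes are chosen with `nextn()`.
* GLCM quantization is the native 256 levels for LBP code images;
  matrices are unsymmetrized, so the 8-direction set contains 4
  transpose-redundant pairs — all 8 are kept to honor the declared
  design.
* Seeds derive from one master seed via a fixed integer recurrence and
  stay below 2³¹.

## Problem sizes used by the tests

The property and acceptance suites run at sizes chosen to exercise the
design while keeping a full run in minutes: dimensional contracts on a
64×64 ROI; the evaluation-design checks on the full default cohort (90
sites, 256×384 frames); parameter-recovery and null-calibration LOSO on
30-site cohorts at 128×192; ANOVA type-I calibration on 200 null cohorts
and power on 100 strong-effect cohorts, both at 128×192 with site-level
units.  These sizes are stated here as the package's simulation design;
the generator accepts the full-scale settings unchanged.

## Known limitations

* The phantom's simplifications listed above; in particular, no claim is
  made about clinical classification accuracy.
* The sum-normalized reading of the seven statistics makes some of them
  location- rather than intensity-sensitive on image input (see above);
  the GLCM-style alternative orderings are exposed as options but not the
  default.
* The random-forest grid collapses to Gini splitting (implementation
  availability), and `entropy`/`log_loss` are one criterion for trees.
* Majority voting assumes at least 3 voters and reports, not resolves,
  the tie rate.
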