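---
title: "Box-seeded Chan-Vese segmentation: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box-seeded Chan-Vese segmentation: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvseg)
```

## The problem and the pipeline

Delineating a brain tumor on an axial MRI slice is hard for purely
gradient-based edge detectors: magnitude MR images carry Rician noise, and a
tumor boundary is a *region* transition (bright mass against darker brain
matter), not a clean intensity gradient. `cvseg` implements the mathematics
of a three-stage cascade built around that observation:

1. **Localization.** A region proposal network (RPN) scores a family of
   reference boxes ("anchors") at each position of a downsampled
   (128 x 128) slice and regresses box offsets. The package implements the
   defined mathematics of this stage — anchor generation, IoU-threshold
   labeling, the center/log-size box encoding, and the two-term RPN loss —
   without any training machinery. For end-to-end runs a surrogate
   localizer (`oracle_localizer()`) jitters the known true box, standing in
   for a trained detector.
2. **Contouring.** The detected box is mapped back to the 512 x 512 frame
   (`map_box()`), the crop is contrast-stretched and
   histogram-equalized (`enhance()`), and a morphological Chan-Vese
   active contour is run *only inside the box* (`segment_tumor()`),
   seeded with a square level set.
3. **Evaluation.** The resulting mask is scored against ground truth with
   the full metric suite: Dice, Rand index (pixel-agreement form), variation
   of information, global consistency error, boundary displacement error,
   PSNR and MAE, plus classification utilities (sensitivity/specificity/
   PPV/NPV/accuracy, Cohen's kappa, ROC/AUC).

Everything runs on seeded synthetic phantoms (`generate_phantom()`), so the
whole cascade is exercisable and testable without external data or trained
weights.

## The Chan-Vese model

The contour minimizes the two-phase piecewise-constant fitting energy

$$E(c_1, c_2, C) = \mu\,\mathrm{Length}(C)
  + \lambda_1 \int_{\text{inside}(C)} (u_0 - c_1)^2
  + \lambda_2 \int_{\text{outside}(C)} (u_0 - c_2)^2,$$

where $u_0$ is the crop intensity and $c_1, c_2$ are the mean intensities
inside and outside the contour. Because the energy compares each pixel to
*region statistics* rather than to local gradients, the minimizer locates
boundaries even when noise destroys the gradient signal.

The package uses the morphological formulation: the level set is a binary
field, and one iteration of `evolve_step()` applies

- a **region force** — a pixel joins the foreground exactly when
  $\lambda_1 (u_0 - c_1)^2 < \lambda_2 (u_0 - c_2)^2$ at its location
  (ties go to the background), which is the discrete minimizer of the two
  integral terms for fixed $(c_1, c_2)$; then
- **curvature smoothing** — `n_smooth` applications of the alternating
  $SI \circ IS$ / $IS \circ SI$ operator pair, where $SI$ is the
  sup-of-inf and $IS$ the inf-of-sup over 3-pixel line segments in four
  orientations. These compositions approximate mean-curvature motion of
  the binary front and are parameter-free, which is why the morphological
  scheme needs no explicit $\mu$ term during evolution.

`cv_energy()` reports the discrete energy (contour length counted as
4-neighbor foreground/background adjacencies). Its default `mu` is 0 for
the reporting path because the smoothing operators play the curvature role;
`mu` is retained so the length term can be inspected diagnostically.

### Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `lam1`, `lam2` | 1, 1 | Region weights; the symmetric choice is the standard one for two-phase segmentation and is what the cascade uses throughout. |
| `n_iter` | 100 | Evolution iterations; on box-cropped phantoms the front converges in well under 100 iterations, so the default is a safe ceiling. |
| `n_smooth` | 8 | Smoothing applications per iteration; higher values shorten and regularize the contour. 8 balances noise suppression against corner rounding at the 100-400 px crop sizes the cascade produces. |
| `init_margin_frac` | 0.1 | Inset of the initial square from the crop border. The seeding box already brackets the tumor, so a thin margin suffices; `0` degenerates to a one-pixel border. |
| `alternate` | `"within"` | Whether the two smoothing compositions alternate inside each iteration's `n_smooth` applications or across iterations. Alternating within keeps the curvature flow unbiased even for odd `n_smooth`; the switch exists because either discipline is defensible. |

A square initialization is used rather than the customary circle because
the seed region *is* a box: the contour starts from the geometry the
localizer actually provides.

### Degenerate inputs

On a constant crop the region force has no preference and would empty the
foreground; `evolve_step()` then reverts to its pre-step support and skips
smoothing, so `run_chan_vese()` returns the initialization mask instead of
failing. The same recovery applies whenever an update empties either
region, which keeps 100-iteration runs total on adversarial crops.

## The localization mathematics

`generate_anchors()` produces one anchor per (scale, aspect-ratio) pair —
the default 3 scales x ratios {0.5, 1, 2} give the standard nine anchors,
each of area scale². `label_anchors()` applies the IoU rule: best overlap
above 0.7 is positive, below 0.3 negative, anything between is ignored for
learning, as are boxes crossing the image boundary. `rpn_loss()` evaluates

$$L = \frac{1}{N_{cls}} \sum_i L_{cls}(p_i, p_i^*)
  + \frac{\lambda}{N_{reg}} \sum_i p_i^*\, L_{reg}(t_i, t_i^*),$$

with binary log loss for $L_{cls}$ and smooth-L1 for the robust $L_{reg}$
(the conventional choice; quadratic inside unit residual, linear outside).
The $p_i^*$ gate disables regression for every non-positive anchor. Two
numerical choices: predicted probabilities are clamped to
$[10^{-12}, 1 - 10^{-12}]$ so saturated predictions yield large finite
loss, and $N_{cls}$ defaults to the count of non-ignored anchors (the
minibatch-size reading is available by setting `batch$n_cls` explicitly).

## What the phantom emulates — and what it does not

`generate_phantom()` composes a piecewise-constant axial-slice caricature:
a bright skull ring (intensity 0.95) around a brain disk (0.35), two dark
ventricle-like lobes (0.08) flanking the slice center, a brighter
elliptical tumor (0.80), and near-black air (0.02), then applies Rician
magnitude noise: each clean value $A$ becomes
$\sqrt{(A + n_1)^2 + n_2^2}$ with $n_1, n_2 \sim N(0, \sigma^2)$, the
standard magnitude-image noise model (Rayleigh in the zero-signal limit),
clipped back to $[0,1]$. The default $\sigma = 0.05$ — mid-range of the
0.02–0.1 band the generator is designed for — is a calibration choice: real
acquisitions do not come with a printed noise level, and 0.05 gives a
clearly visible grain (SNR ≈ 7 on brain matter) without destroying the
tumor/brain contrast.

The phantom deliberately reproduces the *failure-mode geometry* that
matters for a box-seeded contour: high-intensity skull close to the brain
boundary and dark ventricles near plausible tumor sites, so a drifting box
or a leaky contour is punished the way it would be on real data. It does
**not** emulate bias fields, partial-volume effects, texture inside the
tumor, anatomy variability, or k-space artifacts. Passing the phantom
suite therefore demonstrates the correctness and noise robustness of the
algorithmic chain, not clinical-grade performance; the headline numbers on
real cohorts depend on a trained localizer and expert ground truth, which
are out of scope here.

Default tumor geometry in `run_cascade()` is drawn per case: center in an
annulus 0.16–0.26 of the frame from the slice center (clear of the
ventricles), semi-axes 7–10% and 5–7.5% of the frame, uniform orientation.
The surrogate localizer expands the true box by `margin_frac = 0.15` per
side before jittering — a detector's box encloses its object with context —
and jitters each edge by up to `jitter_frac` (10% by default) of the box
side.

## Preprocessing choices

"Intensity normalization to [0, 1]" is implemented as per-image min-max
rescaling (`rescale_intensity()`); a constant image maps to zeros.
Downsampling is block-mean with integer factors only — anti-aliased and
exactly oracle-checkable. Contrast enhancement is a 2nd–98th percentile
stretch followed by 256-bin histogram equalization; both maps are
monotone, and a constant crop passes through unchanged to avoid a
divide-by-zero in the CDF normalization. Boxes use a 0-based, half-open
`(r0, c0, r1, c1)` convention so areas and IoU are exact integer
arithmetic on pixel-grid boxes, and the 128→512 coordinate mapping is
exactly invertible for integer scale factors.

## Metric conventions

- **Rand index** is computed exactly as the pixel-agreement fraction
  `(TP + TN) / total` — the form used alongside the confusion-matrix
  quantities here — not the pair-counting Rand index of the clustering
  literature; the two agree at 1 for identical masks.
- **VOI** uses natural-log entropies from the joint 2x2 histogram (a
  `base` argument switches to bits).
- **GCE** treats the binary class regions as the segments when evaluating
  the local refinement error.
- **BDE** is the symmetric mean nearest-boundary distance (directed
  variants exposed); boundary pixels are foreground pixels with a
  4-neighbor background pixel, the frame border counting as background.
- **MAE/PSNR** operate on the 0–255 display scale (configurable); both
  mask-vs-mask and image-vs-image comparisons are supported, and PSNR
  returns `Inf` for identical inputs.
- **Dice** of two empty masks is defined as 1 (perfect-agreement limit).
- **AUC** is the trapezoid area under the threshold-swept ROC and equals
  the Mann–Whitney pairwise-concordance statistic.

The Prewitt baseline needs a rule for turning an open edge map into a
comparable mask: the gradient magnitude is thresholded at 30% of its
maximum, the edge map is morphologically closed (3x3 box), enclosed holes
are filled, and the largest connected component is kept. An empty result
is a warning, not an error, so suite runs continue.

## Problem sizes and determinism

The package's own validation suite runs the full cascade on twenty
512 x 512 phantoms at $\sigma = 0.05$ with 10% box jitter (both contour
and baseline arms), plus property sweeps on small random masks — sizes
chosen so the whole suite completes in a few minutes on one core while
still exercising full-resolution geometry. Every random draw flows through
an explicit seed (`with_seed()` restores the caller's RNG state), so
phantom generation, the cascade, and both segmenters are bit-reproducible:
two runs from one `run_config()` write byte-identical summaries.

## Known limitations

- Two-phase contours only: a single foreground region per box; no
  multiphase Chan-Vese.
- The morphological scheme's smoothing strength is quantized by
  `n_smooth`; there is no continuous curvature weight during evolution.
- The energy trace is reported for the monitored `cv_params()` (default
  `mu = 0`); it is a diagnostic, not the quantity the discrete operators
  minimize exactly, so small non-monotonic wiggles between iterations are
  possible even though runs end at or below their starting energy in
  practice.
- `map_box()` restricts to integer resolution factors; arbitrary
  rescaling would need resampling rules the pipeline does not require.
- The phantom's realism limits are listed above; none of the package's
  numbers should be read as clinical performance claims.
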