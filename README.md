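# cvseg

Box-seeded tumor segmentation toolkit for axial MRI-like images.

Gradient edge detectors (Prewitt, Sobel) underperform on magnitude MR
images: the noise is Rician and tumor boundaries are region transitions
rather than clean intensity gradients. `cvseg` implements the mathematics
of a cascade that addresses this: a localization stage proposes a bounding
box around the tumor, and a **morphological Chan–Vese active contour**,
seeded with a square level set inside that box, extracts the precise
boundary. The package provides

- the region-proposal (RPN) mathematics of the localization stage —
  anchor generation (the standard 9 anchors from 3 scales x aspect ratios
  {0.5, 1, 2}), IoU labeling at the 0.7/0.3 thresholds, center/log-size
  box encoding, and the gated two-term RPN loss — as standalone,
  training-free functions;
- the morphological Chan–Vese segmenter minimizing the two-phase energy
  `mu·Length(C) + lam1·∫_inside (u0−c1)² + lam2·∫_outside (u0−c2)²`
  (defaults `lam1 = lam2 = 1`, 100 iterations, 8 smoothing applications
  per iteration), plus a Prewitt gradient baseline for comparison;
- the full evaluation suite: Dice `2TP/(2TP+FP+FN)`, Rand index
  `(TP+TN)/total`, variation of information `H(Sg)+H(St)−2MI`, global
  consistency error, boundary displacement error, PSNR, MAE, and
  classification metrics (Sn/Sp/PPV/NPV/accuracy, Cohen's kappa,
  ROC/AUC);
- a seeded synthetic phantom generator — elliptical tumor, brain disk,
  skull ring, ventricle distractors, Rician magnitude noise — with exact
  ground-truth masks and boxes, so the entire cascade runs and is tested
  without external data or trained weights.

See the vignette (`vignettes/box-seeded-segmentation.Rmd`) for the model,
parameter rationale, and design decisions.

## Worked example

```r
library(cvseg)

# a 256x256 phantom slice: bright elliptical tumor, skull ring,
# ventricle distractors, Rician noise sigma = 0.08
spec <- phantom_spec(image_size = 256L, tumor_center = c(165, 150),
                     tumor_axes = c(22, 16), tumor_angle = 0.5,
                     rician_sigma = 0.08, seed = 11L)
ph <- generate_phantom(spec)

# surrogate localizer: true box + 15% margin, edges jittered by up to 10%
box <- oracle_localizer(ph$truth, jitter_frac = 0.1, margin_frac = 0.15,
                        seed = 11L)
box
#> <bbox [136,187) x [127,169), conf 0.939>

mask <- segment_tumor(ph$image, box, cv_params())     # Chan-Vese in the box
rep  <- metrics_report(mask, ph$truth$mask)
#> dice 1.0000  RI 1.0000  VOI 0.0000  GCE 0.00000  BDE 0.000

baseline <- segment_tumor(ph$image, box, method = "prewitt")
dice(confusion_counts(baseline, ph$truth$mask))
#> [1] 0.8868
```

The contour recovers the rasterized tumor exactly on this slice — the
phantom is piecewise-constant, so with the box in place the region force
classifies every pixel correctly despite the noise — while the gradient
baseline leaks (Dice 0.89, boundary displacement 2.25 px vs 0).

On the package's standard suite (20 seeded 512x512 phantoms, noise
sigma = 0.05, 10% box jitter; `compare_methods(run_config(seed = 2026))`):

| method   | Dice  | RI     | VOI    | GCE     | BDE   | PSNR  | MAE   |
|----------|-------|--------|--------|---------|-------|-------|-------|
| chanvese | 0.996 | 0.9999 | 0.0022 | 0.00029 | 0.18  | 39.0  | 0.037 |
| prewitt  | 0.678 | 0.982  | 0.107  | 0.0153  | 12.90 | 18.6  | 4.52  |

Higher Dice/RI and lower VOI/GCE/BDE/MAE are better; the region-based
contour dominates the gradient baseline on every metric on this noisy
suite.

## Command line

A thin front end over the package lives at `inst/cli/cvseg`:

```sh
cvseg simulate --n 5 --seed 1 --outdir phantoms/      # images, masks, truth.json
cvseg segment  --image img.tiff --box 284,208,408,300 --method chanvese \
               --iters 100 --smooth 8 --out mask.png --trace energy.csv
cvseg evaluate --pred mask.png --truth truth.png --report report.json
cvseg anchors  --center 320,320                       # 9 anchor boxes as JSON
cvseg cascade  --config cfg.yaml --outdir run/
cvseg compare  --config cfg.yaml --outdir run/
```

Images are 16-bit TIFF (or PNG), masks 0/255 PNG, reports JSON,
summaries CSV.

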