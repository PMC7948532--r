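#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,truth Logical matrices of the same shape; `truth` is the
#'   reference (gold-standard) mask.
#' @return A `confusion_counts` list `(tp, fp, fn, tn)` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot_mask(pred); stopifnot_mask(truth)
  stopifnot_same_shape(pred, truth)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  structure(list(tp = tp, fp = fp, fn = fn,
                 tn = length(pred) - tp - fp - fn),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param tp,fp,fn,tn Nonnegative counts (cases or pixels).
#' @export
counts <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be nonnegative")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Dice score (F1) from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`, in `[0, 1]`; 1 signifies the highest
#' similarity (identical masks). When both masks are empty the score is
#' defined as 1 (perfect-agreement limit).
#'
#' @param counts A `confusion_counts`.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) return(1)
  2 * counts$tp / denom
}

#' Rand index, pixel-agreement form
#'
#' `(TP + TN) / (TP + FP + FN + TN)`: the fraction of pixels whose
#' foreground/background labeling agrees between the two segmentations.
#' Note this is the per-pixel agreement fraction, not the classic
#' pair-counting Rand index of the clustering literature; the two coincide
#' at 1 for identical masks.
#'
#' @param counts A `confusion_counts`.
#' @return Scalar in `[0, 1]`.
#' @export
rand_index <- function(counts) {
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n == 0) stop("empty confusion table")
  (counts$tp + counts$tn) / n
}

# Joint 2x2 label distribution of two masks.
joint_2x2 <- function(pred, truth) {
  stopifnot_mask(pred); stopifnot_mask(truth)
  stopifnot_same_shape(pred, truth)
  n <- length(pred)
  c(n11 = sum(pred & truth), n10 = sum(pred & !truth),
    n01 = sum(!pred & truth), n00 = sum(!pred & !truth)) / n
}

entropy_nats <- function(p, base = exp(1)) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Variation of information between two segmentations
#'
#' `VOI = H(Sg) + H(St) - 2 MI(Sg, St)` from the joint 2x2 pixel-label
#' histogram: the information-theoretic distance between the two
#' labelings. Zero iff they are identical up to label permutation; never
#' exceeds `H(Sg) + H(St)`. Natural-log entropies by default.
#'
#' @param pred,truth Logical matrices of the same shape.
#' @param base Logarithm base (default `exp(1)`; use 2 for bits).
#' @return Nonnegative scalar.
#' @export
voi <- function(pred, truth, base = exp(1)) {
  p <- joint_2x2(pred, truth)
  hp <- entropy_nats(c(p["n11"] + p["n10"], p["n01"] + p["n00"]), base)
  ht <- entropy_nats(c(p["n11"] + p["n01"], p["n10"] + p["n00"]), base)
  hj <- entropy_nats(p, base)
  mi <- hp + ht - hj
  max(0, hp + ht - 2 * mi)
}

#' Global consistency error
#'
#' Measures how far each segmentation is from being a refinement of the
#' other. For pixel `p`, the local refinement error is
#' `E(S1, S2, p) = |R(S1, p) \ R(S2, p)| / |R(S1, p)|` with `R(S, p)` the
#' class region of `S` containing `p` (for binary masks, the full
#' foreground or background class). GCE is the smaller of the two directed
#' error sums, divided by the pixel count; symmetric by construction and 0
#' for identical masks.
#'
#' @param pred,truth Logical matrices of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
gce <- function(pred, truth) {
  stopifnot_mask(pred); stopifnot_mask(truth)
  stopifnot_same_shape(pred, truth)
  n <- length(pred)
  directed <- function(s1, s2) {
    tot <- 0
    for (a in c(TRUE, FALSE)) {
      r1 <- s1 == a
      sz1 <- as.numeric(sum(r1))
      if (sz1 == 0) next
      for (b in c(TRUE, FALSE)) {
        # pixels with labels (a in s1, b in s2) each contribute
        # |R1 \ R2| / |R1| where R2 is s2's class-b region
        np <- as.numeric(sum(r1 & (s2 == b)))
        if (np == 0) next
        excl <- as.numeric(sum(r1 & (s2 != b)))
        tot <- tot + np * excl / sz1
      }
    }
    tot
  }
  min(directed(pred, truth), directed(truth, pred)) / n
}

# Boundary pixels: foreground pixels with a 4-neighbor background pixel
# (the frame border counts as background).
boundary_pixels <- function(mask) {
  stopifnot_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(inner & !nb, arr.ind = TRUE)
}

#' Boundary displacement error
#'
#' Average displacement between the boundary pixels of two masks: for each
#' boundary pixel of one mask, the Euclidean distance to the nearest
#' boundary pixel of the other, averaged over that boundary; the symmetric
#' value is the mean of the two directed averages. Zero iff the boundaries
#' coincide.
#'
#' @param pred,truth Logical matrices of the same shape, each with a
#'   nonempty boundary.
#' @param directed `"both"` (symmetric, default), `"pred_to_truth"`, or
#'   `"truth_to_pred"`.
#' @return Nonnegative scalar, in pixels.
#' @export
bde <- function(pred, truth,
                directed = c("both", "pred_to_truth", "truth_to_pred")) {
  directed <- match.arg(directed)
  stopifnot_same_shape(pred, truth)
  bp <- boundary_pixels(pred)
  bt <- boundary_pixels(truth)
  if (nrow(bp) == 0L || nrow(bt) == 0L) stop("a mask has an empty boundary")
  one_way <- function(a, b) {
    # min over b of Euclidean distance, per row of a
    d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
    mean(sqrt(apply(d2, 1L, min)))
  }
  switch(directed,
         pred_to_truth = one_way(bp, bt),
         truth_to_pred = one_way(bt, bp),
         both = (one_way(bp, bt) + one_way(bt, bp)) / 2)
}

#' Mean absolute error on the 0-255 scale
#'
#' Mean absolute pixelwise difference between two images or masks. Inputs
#' are brought to the `[0, max_value]` display scale first: logical masks
#' become `0 / max_value`, numeric images in `[0, 1]` are multiplied by
#' `max_value`.
#'
#' @param pred_img,truth_img Numeric matrices in `[0, 1]` or logical
#'   masks, same shape.
#' @param max_value Display scale maximum (default 255).
#' @return Nonnegative scalar.
#' @export
mae <- function(pred_img, truth_img, max_value = 255) {
  a <- to_display_scale(pred_img, max_value)
  b <- to_display_scale(truth_img, max_value)
  stopifnot_same_shape(a, b)
  mean(abs(a - b))
}

to_display_scale <- function(x, max_value) {
  if (is.logical(x)) x <- x * 1
  x * max_value
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX^2 / MSE)` on the display scale, in decibels. Identical
#' inputs give `Inf` (zero mean squared error).
#'
#' @inheritParams mae
#' @return Scalar in dB; `Inf` for identical inputs.
#' @export
psnr <- function(pred_img, truth_img, max_value = 255) {
  a <- to_display_scale(pred_img, max_value)
  b <- to_display_scale(truth_img, max_value)
  stopifnot_same_shape(a, b)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Classification ratios from a confusion table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values `TP/(TP+FP)` and `TN/(TN+FN)`, and accuracy
#' `(TP+TN)/total`. A ratio whose denominator is zero is reported as `NA`
#' rather than 0.
#'
#' @param counts A `confusion_counts`.
#' @return Named list of the five ratios.
#' @export
classification_metrics <- function(counts) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = ratio(tp + tn, tp + fp + fn + tn)
  ))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with `p_o` the
#' observed agreement fraction and `p_e` the agreement expected from the
#' marginal frequencies. Robust to class imbalance; 1 for perfect
#' agreement, 0 when predictions are independent of truth. Degenerate
#' marginals (`p_e = 1`) give `NA`.
#'
#' @param counts A `confusion_counts`.
#' @return Scalar in `[-1, 1]`, or `NA`.
#' @export
cohen_kappa <- function(counts) {
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n == 0) stop("empty confusion table")
  po <- (counts$tp + counts$tn) / n
  pe <- ((counts$tp + counts$fp) * (counts$tp + counts$fn) +
           (counts$fn + counts$tn) * (counts$fp + counts$tn)) / n^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique scores (predicting
#' positive when `score >= threshold`), collecting (false positive rate,
#' true positive rate) pairs from `(0,0)` to `(1,1)`; the area is computed
#' by the trapezoid rule and equals the Mann-Whitney pairwise-concordance
#' probability.
#'
#' @param scores Numeric prediction scores, higher meaning more positive.
#' @param labels Binary truth labels (0/1 or logical); both classes must
#'   be present.
#' @return List with `curve` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & labels == 0L) / nn,
      tpr = sum(pred & labels == 1L) / np)
  }, numeric(2L)))
  curve <- as.data.frame(pts)
  o <- order(curve$fpr, curve$tpr)
  curve <- curve[o, , drop = FALSE]
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1L) +
                                  utils::tail(curve$tpr, -1L)) / 2)
  list(curve = curve, auc = auc)
}

#' Full segmentation metric report for one (predicted, truth) pair
#'
#' Computes all seven segmentation quantities (Dice, Rand index, VOI,
#' GCE, BDE, PSNR, MAE) between a predicted and a reference mask.
#' BDE requires both boundaries to be nonempty; when the prediction is
#' empty it is reported as `NA`.
#'
#' @param pred,truth Logical masks of the same shape.
#' @param params Optional named list echoed into the report for
#'   provenance.
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(pred, truth, params = list()) {
  cc <- confusion_counts(pred, truth)
  b <- tryCatch(bde(pred, truth), error = function(e) NA_real_)
  structure(list(
    dice = dice(cc), rand_index = rand_index(cc),
    voi = voi(pred, truth), gce = gce(pred, truth), bde = b,
    psnr = psnr(pred, truth), mae = mae(pred, truth),
    counts = cc, params = params
  ), class = "metrics_report")
}
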