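#' Generate reference anchors at an image position
#'
#' A region proposal network scores a fixed family of reference boxes
#' ("anchors") at every position. One anchor is produced per (scale,
#' aspect-ratio) pair, centered at the given position: for scale `s` and
#' ratio `rho = h / w` the box has height `s * sqrt(rho)` and width
#' `s / sqrt(rho)`, so its area is `s^2` at every ratio. The default
#' configuration — three scales crossed with ratios 0.5, 1, 2 — yields the
#' standard nine anchors.
#'
#' @param center `(row, col)` anchor position in pixels.
#' @param scales Positive box scales (side of the square ratio-1 anchor).
#' @param ratios Positive height/width aspect ratios.
#' @return A list of anchors; each has `center`, `scale`, `aspect_ratio`
#'   and the derived `box` (`bbox`).
#' @examples
#' length(generate_anchors(c(320, 320))) # 9
#' @export
generate_anchors <- function(center,
                             scales = c(64, 128, 256),
                             ratios = c(0.5, 1, 2)) {
  if (length(scales) == 0L || length(ratios) == 0L) {
    stop("scales and ratios must be nonempty")
  }
  if (any(scales <= 0) || any(ratios <= 0)) {
    stop("scales and ratios must be positive")
  }
  grid <- expand.grid(scale = scales, ratio = ratios,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$scale[i]; rho <- grid$ratio[i]
    h <- s * sqrt(rho); w <- s / sqrt(rho)
    structure(
      list(center = as.numeric(center), scale = s, aspect_ratio = rho,
           box = bbox(center[1L] - h / 2, center[2L] - w / 2,
                      center[1L] + h / 2, center[2L] + w / 2)),
      class = "anchor"
    )
  })
}

#' Assign positive/negative/ignore labels to anchors
#'
#' An anchor whose best IoU against any ground-truth box exceeds `hi` is
#' labeled positive (its regression target `p*` is 1); below `lo` it is
#' negative (`p*` = 0); in between it is ignored and contributes to neither
#' loss term. Anchors whose box crosses the image boundary are also
#' ignored when a `frame` is supplied.
#'
#' @param anchors List of anchors from [generate_anchors()].
#' @param gt_boxes Nonempty list of ground-truth `bbox`es.
#' @param hi,lo IoU thresholds (defaults 0.7 and 0.3; `hi > lo` required).
#' @param frame Optional `(rows, cols)` image size; anchors not fully
#'   inside are labeled `"ignore"`.
#' @return Character vector over anchors with values `"positive"`,
#'   `"negative"`, `"ignore"`.
#' @export
label_anchors <- function(anchors, gt_boxes, hi = 0.7, lo = 0.3,
                          frame = NULL) {
  if (length(gt_boxes) == 0L) stop("gt_boxes must be nonempty")
  if (hi <= lo) stop("need hi > lo")
  vapply(anchors, function(a) {
    b <- if (inherits(a, "anchor")) a$box else a
    if (!is.null(frame) &&
        (b$r0 < 0 || b$c0 < 0 || b$r1 > frame[1L] || b$c1 > frame[2L])) {
      return("ignore")
    }
    best <- max(vapply(gt_boxes, function(g) iou(b, g), numeric(1L)))
    if (best > hi) "positive" else if (best < lo) "negative" else "ignore"
  }, character(1L))
}

anchor_geom <- function(anchor) {
  b <- if (inherits(anchor, "anchor")) anchor$box else anchor
  list(h = b$r1 - b$r0, w = b$c1 - b$c0,
       cy = (b$r0 + b$r1) / 2, cx = (b$c0 + b$c1) / 2)
}

#' Parameterize a box relative to an anchor
#'
#' Standard center/log-size encoding of a target box against its anchor:
#' `t = ((cx - cxa)/wa, (cy - cya)/ha, log(w/wa), log(h/ha))` where
#' `(cx, cy, w, h)` describe the box and `(cxa, cya, wa, ha)` the anchor.
#' Encoding the anchor's own box gives the zero vector, and
#' [decode_box()] inverts the encoding exactly.
#'
#' @param anchor An anchor (or bare `bbox`) providing the reference frame.
#' @param box Target `bbox`.
#' @return Numeric 4-vector `t`.
#' @export
parameterize_box <- function(anchor, box) {
  a <- anchor_geom(anchor); g <- anchor_geom(box)
  if (a$w <= 0 || a$h <= 0 || g$w <= 0 || g$h <= 0) {
    stop("boxes must have positive extent")
  }
  c((g$cx - a$cx) / a$w, (g$cy - a$cy) / a$h,
    log(g$w / a$w), log(g$h / a$h))
}

#' @rdname parameterize_box
#' @param t Encoding produced by [parameterize_box()].
#' @return `decode_box()`: the `bbox` whose encoding against `anchor` is
#'   `t`.
#' @export
decode_box <- function(anchor, t) {
  a <- anchor_geom(anchor)
  cx <- t[1L] * a$w + a$cx; cy <- t[2L] * a$h + a$cy
  w <- exp(t[3L]) * a$w; h <- exp(t[4L]) * a$h
  bbox(cy - h / 2, cx - w / 2, cy + h / 2, cx + w / 2)
}

#' Smooth-L1 robust loss
#'
#' Per coordinate `0.5 x^2` for `|x| < 1` and `|x| - 0.5` otherwise,
#' summed over the vector: quadratic near zero, linear in the tails, so
#' large residuals are not penalized quadratically. This is the robust
#' regression loss used for box offsets.
#'
#' @param x Numeric vector of residuals.
#' @return Nonnegative scalar; zero iff `x` is the zero vector.
#' @export
smooth_robust_loss <- function(x) {
  sum(ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5))
}

#' Region-proposal-network training loss
#'
#' Two-term objective over a minibatch of anchors: a mean binary log loss
#' over the labeled (non-ignored) anchors for objectness, plus a
#' smooth-L1 regression term over box encodings, weighted by `lambda /
#' n_reg` and gated by `p_star` so only positive anchors contribute
#' regression loss. Predicted probabilities are clamped to
#' `[eps, 1 - eps]` so saturated predictions give a large finite loss.
#'
#' @param batch List with elements: `p` predicted objectness per anchor in
#'   `(0, 1)`; `p_star` per-anchor labels (1 positive, 0 negative, `NA`
#'   ignored); `t` and `t_star` numeric matrices, one 4-vector row per
#'   anchor (rows for non-positive anchors are ignored); optional `n_cls`
#'   classification normalizer (defaults to the number of labeled
#'   anchors); `n_reg` regression normalizer (defaults to the number of
#'   anchors); `lambda` balance weight (default 1).
#' @param eps Clamp width for the log loss.
#' @return Scalar loss.
#' @export
rpn_loss <- function(batch, eps = 1e-12) {
  p <- batch$p; ps <- batch$p_star
  labeled <- !is.na(ps)
  if (!any(labeled)) stop("batch has no labeled anchors")
  n_cls <- if (!is.null(batch$n_cls)) batch$n_cls else sum(labeled)
  n_reg <- if (!is.null(batch$n_reg)) batch$n_reg else length(p)
  lambda <- if (!is.null(batch$lambda)) batch$lambda else 1
  if (n_cls < 1 || n_reg < 1) stop("normalizers must be >= 1")

  pc <- pmin(pmax(p[labeled], eps), 1 - eps)
  cls <- sum(-(ps[labeled] * log(pc) + (1 - ps[labeled]) * log(1 - pc))) / n_cls

  pos <- which(!is.na(ps) & ps == 1)
  reg <- 0
  if (length(pos) > 0L) {
    tt <- rbind(batch$t)[pos, , drop = FALSE]
    ts <- rbind(batch$t_star)[pos, , drop = FALSE]
    reg <- sum(vapply(seq_along(pos), function(i) {
      smooth_robust_loss(tt[i, ] - ts[i, ])
    }, numeric(1L)))
  }
  cls + lambda * reg / n_reg
}
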