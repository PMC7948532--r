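# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain loops over pixels, sharing no code with the
# package's vectorized implementations.

bf_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1L
    else if (pred[i] && !truth[i]) fp <- fp + 1L
    else if (!pred[i] && truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

bf_dice <- function(pred, truth) {
  cc <- bf_confusion(pred, truth)
  d <- 2 * cc$tp + cc$fp + cc$fn
  if (d == 0) 1 else 2 * cc$tp / d
}

bf_rand_index <- function(pred, truth) {
  cc <- bf_confusion(pred, truth)
  (cc$tp + cc$tn) / (cc$tp + cc$fp + cc$fn + cc$tn)
}

bf_voi <- function(pred, truth) {
  n <- length(pred)
  p11 <- p10 <- p01 <- p00 <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) p11 <- p11 + 1
    else if (pred[i] && !truth[i]) p10 <- p10 + 1
    else if (!pred[i] && truth[i]) p01 <- p01 + 1
    else p00 <- p00 + 1
  }
  pj <- c(p11, p10, p01, p00) / n
  h <- function(ps) { s <- 0; for (p in ps) if (p > 0) s <- s - p * log(p); s }
  hp <- h(c(p11 + p10, p01 + p00) / n)
  ht <- h(c(p11 + p01, p10 + p00) / n)
  mi <- hp + ht - h(pj)
  hp + ht - 2 * mi
}

# Per-pixel set computation of the local refinement error.
bf_gce <- function(pred, truth) {
  n <- length(pred)
  err_sum <- function(s1, s2) {
    tot <- 0
    for (i in seq_len(n)) {
      r1 <- which(as.vector(s1) == s1[i])
      r2 <- which(as.vector(s2) == s2[i])
      tot <- tot + length(setdiff(r1, r2)) / length(r1)
    }
    tot
  }
  min(err_sum(pred, truth), err_sum(truth, pred)) / n
}

bf_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    # a 4-neighbor outside the frame counts as background
    nb_bg <- FALSE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) {
        nb_bg <- TRUE
      }
    }
    if (nb_bg) out <- rbind(out, c(r, c))
  }
  out
}

bf_bde <- function(pred, truth) {
  bp <- bf_boundary(pred); bt <- bf_boundary(truth)
  one <- function(a, b) {
    tot <- 0
    for (i in seq_len(nrow(a))) {
      best <- Inf
      for (j in seq_len(nrow(b))) {
        d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
        if (d < best) best <- d
      }
      tot <- tot + best
    }
    tot / nrow(a)
  }
  (one(bp, bt) + one(bt, bp)) / 2
}

bf_mae <- function(pred, truth, max_value = 255) {
  a <- if (is.logical(pred)) pred * max_value else pred * max_value
  b <- if (is.logical(truth)) truth * max_value else truth * max_value
  tot <- 0
  for (i in seq_along(a)) tot <- tot + abs(a[i] - b[i])
  tot / length(a)
}

# Mann-Whitney pairwise concordance probability.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Mean of the Rice(A, sigma) distribution by numerical integration.
bf_rician_mean <- function(A, sigma) {
  f <- function(x) {
    x * (x / sigma^2) * exp(-(x^2 + A^2) / (2 * sigma^2) +
                              abs(x * A / sigma^2)) *
      besselI(x * A / sigma^2, 0, expon.scaled = TRUE)
  }
  stats::integrate(f, 0, A + 12 * sigma, rel.tol = 1e-10)$value
}

# Random mask pair generator for oracle-equivalence sweeps. Guarantees both
# masks have nonempty foreground and background and a nonempty boundary.
random_mask_pair <- function(nr = 8, nc = 8) {
  repeat {
    a <- matrix(stats::runif(nr * nc) < stats::runif(1, 0.2, 0.8), nr, nc)
    b <- matrix(stats::runif(nr * nc) < stats::runif(1, 0.2, 0.8), nr, nc)
    if (any(a) && !all(a) && any(b) && !all(b)) return(list(a = a, b = b))
  }
}

# Disk-on-background test crop used across contour tests.
disk_crop <- function(n = 60, radius = 15, inside = 0.9, outside = 0.2) {
  m <- cvseg::ellipse_mask(n, n, c((n - 1) / 2, (n - 1) / 2),
                           c(radius, radius))
  img <- matrix(outside, n, n)
  img[m] <- inside
  list(image = img, mask = m)
}
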