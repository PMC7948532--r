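#' Parameters for the morphological Chan-Vese contour
#'
#' The Chan-Vese model segments a crop into two regions by minimizing a
#' piecewise-constant fitting energy
#' `mu * Length(C) + lam1 * sum_inside (u0 - c1)^2 + lam2 * sum_outside
#' (u0 - c2)^2`, where `c1`, `c2` are the mean intensities inside and
#' outside the evolving contour `C`. The morphological variant evolves a
#' binary level set with a pointwise region force followed by
#' curvature-smoothing morphological operators, so no PDE is solved.
#'
#' @param mu Curvature weight in the reported energy; the morphological
#'   smoothing plays the curvature role during evolution, so the default
#'   is 0 and `mu` is kept for diagnostics.
#' @param lam1,lam2 Positive region weights (both default 1).
#' @param n_iter Number of evolution iterations (default 100).
#' @param n_smooth Smoothing-operator applications per iteration (default
#'   8).
#' @param init_margin_frac Inset of the initial square from the crop
#'   border, as a fraction of the side; in `[0, 0.5)`.
#' @param alternate `"within"` alternates the two smoothing compositions
#'   inside each iteration's `n_smooth` applications; `"per_iter"` keeps
#'   one composition per iteration and alternates across iterations.
#' @return A `cv_params` object.
#' @export
cv_params <- function(mu = 0, lam1 = 1, lam2 = 1, n_iter = 100L,
                      n_smooth = 8L, init_margin_frac = 0.1,
                      alternate = c("within", "per_iter")) {
  alternate <- match.arg(alternate)
  if (lam1 <= 0 || lam2 <= 0) stop("lam1 and lam2 must be positive")
  if (n_iter < 0 || n_smooth < 0) stop("n_iter and n_smooth must be >= 0")
  if (mu < 0) stop("mu must be >= 0")
  if (init_margin_frac < 0 || init_margin_frac >= 0.5) {
    stop("init_margin_frac must lie in [0, 0.5)")
  }
  structure(list(mu = mu, lam1 = lam1, lam2 = lam2,
                 n_iter = as.integer(n_iter),
                 n_smooth = as.integer(n_smooth),
                 init_margin_frac = init_margin_frac,
                 alternate = alternate),
            class = "cv_params")
}

#' Square level-set initialization
#'
#' The contour is seeded as a centered axis-aligned square because the
#' seeding boxes are themselves (near-)square: the initial foreground is
#' the square inset by `margin_frac` of the side from each crop border.
#' With `margin_frac = 0` the inset still keeps a one-pixel background
#' border so both regions are nonempty.
#'
#' @param crop_shape `(rows, cols)` of the crop; both at least 3.
#' @param margin_frac Fractional inset per side, in `[0, 0.5)`.
#' @return A `level_set_state`: list with binary matrix `u` (1 =
#'   foreground/inside), `iteration`, and `energy_trace`.
#' @export
init_square <- function(crop_shape, margin_frac = 0.1) {
  nr <- crop_shape[1L]; nc <- crop_shape[2L]
  if (nr < 3L || nc < 3L) stop("crop must be at least 3x3")
  if (margin_frac < 0 || margin_frac >= 0.5) {
    stop("margin_frac must lie in [0, 0.5)")
  }
  ir <- max(1L, as.integer(floor(margin_frac * nr)))
  ic <- max(1L, as.integer(floor(margin_frac * nc)))
  if (ir >= nr - ir || ic >= nc - ic) stop("crop too small for this margin")
  u <- matrix(0L, nr, nc)
  u[(ir + 1):(nr - ir), (ic + 1):(nc - ic)] <- 1L
  structure(list(u = u, iteration = 0L, energy_trace = numeric(0)),
            class = "level_set_state")
}

#' Mean intensities inside and outside the contour
#'
#' @param image_crop Numeric matrix.
#' @param state A `level_set_state` whose `u` has the crop's shape.
#' @return `c(c1, c2)`: mean intensity over the foreground and background.
#' @export
region_means <- function(image_crop, state) {
  u <- state$u
  stopifnot_same_shape(image_crop, u)
  n1 <- sum(u)
  n2 <- length(u) - n1
  if (n1 == 0L || n2 == 0L) stop("a level-set region is empty")
  s1 <- sum(image_crop[u == 1L])
  c(c1 = s1 / n1, c2 = (sum(image_crop) - s1) / n2)
}

# 4-neighbor foreground/background adjacencies: the discrete contour length.
contour_length <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  sum(u[-nr, ] != u[-1L, ]) + sum(u[, -nc] != u[, -1L])
}

#' Discrete Chan-Vese energy of a state
#'
#' `mu * Length(C) + lam1 * sum_inside (u0 - c1)^2 + lam2 * sum_outside
#' (u0 - c2)^2`, with the contour length discretized as the count of
#' 4-adjacent foreground/background pixel pairs.
#'
#' @inheritParams region_means
#' @param params A [cv_params()].
#' @return Nonnegative scalar energy.
#' @export
cv_energy <- function(image_crop, state, params = cv_params()) {
  u <- state$u
  stopifnot_same_shape(image_crop, u)
  cm <- region_means(image_crop, state)
  inside <- u == 1L
  params$mu * contour_length(u) +
    params$lam1 * sum((image_crop[inside] - cm[1L])^2) +
    params$lam2 * sum((image_crop[!inside] - cm[2L])^2)
}

# Morphological curvature operators over the four 3-pixel line segments
# (horizontal, vertical, two diagonals). SI = sup over lines of the inf
# along the line; IS = inf over lines of the sup. Their alternating
# compositions approximate mean-curvature motion of the binary front.
.cv_lines <- list(
  list(c(0L, -1L), c(0L, 1L)),
  list(c(-1L, 0L), c(1L, 0L)),
  list(c(-1L, -1L), c(1L, 1L)),
  list(c(-1L, 1L), c(1L, -1L))
)

si_op <- function(u) {
  best <- NULL
  for (ln in .cv_lines) {
    v <- pmin(u, shift_mat(u, ln[[1L]][1L], ln[[1L]][2L]),
              shift_mat(u, ln[[2L]][1L], ln[[2L]][2L]))
    best <- if (is.null(best)) v else pmax(best, v)
  }
  best
}

is_op <- function(u) {
  best <- NULL
  for (ln in .cv_lines) {
    v <- pmax(u, shift_mat(u, ln[[1L]][1L], ln[[1L]][2L]),
              shift_mat(u, ln[[2L]][1L], ln[[2L]][2L]))
    best <- if (is.null(best)) v else pmin(best, v)
  }
  best
}

smooth_u <- function(u, n_smooth, iteration, alternate) {
  if (n_smooth == 0L) return(u)
  for (k in seq_len(n_smooth)) {
    odd <- if (alternate == "within") k %% 2L == 1L else iteration %% 2L == 1L
    u <- if (odd) si_op(is_op(u)) else is_op(si_op(u))
  }
  u
}

#' One morphological Chan-Vese evolution step
#'
#' Applies the region force — a pixel joins the foreground exactly when
#' `lam1 * (u0 - c1)^2 < lam2 * (u0 - c2)^2` at its location, with `c1`,
#' `c2` the current region means — then `n_smooth` applications of the
#' alternating curvature-smoothing operator pair. If the force would empty
#' either region (e.g. on a constant crop, where it has no preference),
#' the step reverts to its pre-step support and skips smoothing, so runs
#' on degenerate crops stay total. The energy after the step is appended
#' to the trace.
#'
#' @inheritParams cv_energy
#' @return The evolved `level_set_state`.
#' @export
evolve_step <- function(image_crop, state, params = cv_params()) {
  u <- state$u
  stopifnot_same_shape(image_crop, u)
  cm <- region_means(image_crop, state)
  force_in <- params$lam1 * (image_crop - cm[1L])^2 <
    params$lam2 * (image_crop - cm[2L])^2
  u_new <- matrix(0L, nrow(u), ncol(u))
  u_new[force_in] <- 1L
  if (sum(u_new) == 0L || sum(u_new) == length(u_new)) {
    u_new <- u                                   # revert; no smoothing
  } else {
    u_new <- smooth_u(u_new, params$n_smooth, state$iteration + 1L,
                      params$alternate)
    if (sum(u_new) == 0L || sum(u_new) == length(u_new)) u_new <- u
  }
  state$u <- u_new
  state$iteration <- state$iteration + 1L
  state$energy_trace <- c(state$energy_trace,
                          cv_energy(image_crop, state, params))
  state
}

#' Run the morphological Chan-Vese contour on a crop
#'
#' Seeds a square level set, records the initial energy, then applies
#' `n_iter` evolution steps. Fully deterministic: identical crops give
#' bit-identical masks.
#'
#' @param image_crop Numeric matrix, at least 3x3.
#' @param params A [cv_params()].
#' @param return_state If `TRUE`, return the final `level_set_state`
#'   (with the full `energy_trace`, whose first entry is the
#'   initialization energy) instead of the bare mask.
#' @return Logical foreground mask over the crop, or the state.
#' @examples
#' img <- matrix(0.2, 40, 40)
#' img[ellipse_mask(40, 40, c(20, 20), c(9, 9))] <- 0.9
#' mask <- run_chan_vese(img, cv_params(n_iter = 20))
#' sum(mask & ellipse_mask(40, 40, c(20, 20), c(9, 9)))
#' @export
run_chan_vese <- function(image_crop, params = cv_params(),
                          return_state = FALSE) {
  state <- init_square(dim(image_crop), params$init_margin_frac)
  state$energy_trace <- cv_energy(image_crop, state, params)
  for (i in seq_len(params$n_iter)) {
    state <- evolve_step(image_crop, state, params)
  }
  if (return_state) state else state$u == 1L
}

#' Prewitt gradient-edge baseline segmentation
#'
#' The classical gradient route the contour is compared against: Prewitt
#' 3x3 horizontal/vertical kernels give a gradient magnitude, which is
#' thresholded at a fraction of its maximum; the edge map is
#' morphologically closed, enclosed holes are filled, and the largest
#' connected component is returned as the mask. Gradient edges are not
#' closed curves on noisy images, which is exactly the failure mode the
#' region-based contour avoids.
#'
#' @param image_crop Numeric matrix, at least 3x3.
#' @param threshold_frac Threshold as a fraction of the maximum gradient
#'   magnitude (default 0.3).
#' @return Logical mask over the crop; empty (with a warning) when no
#'   region is found.
#' @export
prewitt_segment <- function(image_crop, threshold_frac = 0.3) {
  if (nrow(image_crop) < 3L || ncol(image_crop) < 3L) {
    stop("crop must be at least 3x3")
  }
  g <- prewitt_gradient(image_crop)
  gmax <- max(g)
  if (gmax == 0) {
    warning("zero gradient everywhere; returning empty mask")
    return(matrix(FALSE, nrow(image_crop), ncol(image_crop)))
  }
  edges <- g >= threshold_frac * gmax
  closed <- EBImage::closing(edges * 1, EBImage::makeBrush(3L, "box"))
  filled <- EBImage::fillHull(closed)
  labels <- EBImage::bwlabel(filled)
  labels <- EBImage::imageData(labels)
  if (max(labels) == 0) {
    warning("no enclosed region found; returning empty mask")
    return(matrix(FALSE, nrow(image_crop), ncol(image_crop)))
  }
  sizes <- tabulate(labels[labels > 0])
  labels == which.max(sizes)
}

# Prewitt gradient magnitude via shifted sums (replicate border padding).
prewitt_gradient <- function(x) {
  col_sum <- function(dc) {
    shift_mat(x, -1L, dc) + shift_mat(x, 0L, dc) + shift_mat(x, 1L, dc)
  }
  row_sum <- function(dr) {
    shift_mat(x, dr, -1L) + shift_mat(x, dr, 0L) + shift_mat(x, dr, 1L)
  }
  gx <- col_sum(1L) - col_sum(-1L)
  gy <- row_sum(1L) - row_sum(-1L)
  sqrt(gx^2 + gy^2)
}

#' Segment a tumor inside a localization box
#'
#' The third cascade stage: crop the image to the (pixel-snapped) box,
#' enhance the crop's contrast, run the chosen segmenter, and paste the
#' crop mask back into a full-frame mask that is zero everywhere outside
#' the box.
#'
#' @param image Full-frame numeric matrix in `[0, 1]`.
#' @param box Localization `bbox` in the image frame.
#' @param params [cv_params()] for the contour.
#' @param method `"chanvese"` (default) or `"prewitt"`.
#' @param enhance_method Passed to [enhance()].
#' @param threshold_frac Prewitt threshold fraction.
#' @param return_details If `TRUE`, also return the crop-frame state /
#'   diagnostics.
#' @return Logical full-frame mask, or (with details) a list
#'   `(mask, box, state)` where `state` is the Chan-Vese final state or
#'   `NULL` for Prewitt.
#' @export
segment_tumor <- function(image, box, params = cv_params(),
                          method = c("chanvese", "prewitt"),
                          enhance_method = "both", threshold_frac = 0.3,
                          return_details = FALSE) {
  method <- match.arg(method)
  box <- snap_box(box, dim(image))
  crop <- crop_to_box(image, box)
  crop <- enhance(crop, enhance_method)
  state <- NULL
  if (method == "chanvese") {
    state <- run_chan_vese(crop, params, return_state = TRUE)
    crop_mask <- state$u == 1L
  } else {
    crop_mask <- prewitt_segment(crop, threshold_frac)
  }
  full <- paste_at_box(matrix(FALSE, nrow(image), ncol(image)),
                       crop_mask, box)
  if (return_details) list(mask = full, box = box, state = state) else full
}
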