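#' Specification for a synthetic axial-slice phantom
#'
#' Describes one MRI-like 2D slice: a bright elliptical tumor on darker
#' brain matter, surrounded by a high-intensity skull ring, with two dark
#' ventricle-like distractor lobes near the slice center, all corrupted by
#' Rician magnitude noise. Intensities are on the `[0, 1]` scale.
#'
#' @param image_size Side of the square image in pixels (default 512).
#' @param tumor_center `(row, col)` of the tumor ellipse center, pixels.
#' @param tumor_axes `(a, b)` semi-axes of the tumor ellipse, pixels.
#' @param tumor_angle Rotation of the ellipse major axis, radians.
#' @param tumor_intensity,brain_intensity,skull_intensity,ventricle_intensity
#'   Region intensities in `[0, 1]`.
#' @param background_intensity Intensity outside the skull (air).
#' @param rician_sigma Rician noise scale in intensity units; `>= 0`.
#' @param class_label `"meningioma"` or `"glioma"`.
#' @param seed Integer seed driving the noise draw.
#' @return A `phantom_spec` object.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(image_size = 512L,
                         tumor_center = c(330, 310),
                         tumor_axes = c(45, 34),
                         tumor_angle = 0.4,
                         tumor_intensity = 0.80,
                         brain_intensity = 0.35,
                         skull_intensity = 0.95,
                         ventricle_intensity = 0.08,
                         background_intensity = 0.02,
                         rician_sigma = 0.05,
                         class_label = c("meningioma", "glioma"),
                         seed = 1L) {
  class_label <- match.arg(class_label)
  intens <- c(tumor_intensity, brain_intensity, skull_intensity,
              ventricle_intensity, background_intensity)
  if (any(intens < 0) || any(intens > 1)) stop("intensities must lie in [0, 1]")
  if (rician_sigma < 0) stop("rician_sigma must be >= 0")
  if (any(tumor_axes <= 0)) stop("tumor_axes must be positive")
  structure(
    list(image_size = as.integer(image_size),
         tumor_center = as.numeric(tumor_center),
         tumor_axes = as.numeric(tumor_axes),
         tumor_angle = as.numeric(tumor_angle),
         tumor_intensity = tumor_intensity,
         brain_intensity = brain_intensity,
         skull_intensity = skull_intensity,
         ventricle_intensity = ventricle_intensity,
         background_intensity = background_intensity,
         rician_sigma = rician_sigma,
         class_label = class_label,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Rasterize an ellipse as a binary mask
#'
#' A pixel belongs to the ellipse when its (0-based) center satisfies the
#' implicit inequality `u^2 + v^2 <= 1` in the rotated, axis-scaled frame.
#'
#' @param nrow,ncol Mask dimensions.
#' @param center `(row, col)` ellipse center in 0-based pixel coordinates.
#' @param axes `(a, b)` semi-axes in pixels.
#' @param angle Rotation in radians.
#' @return Logical `nrow x ncol` matrix.
#' @export
ellipse_mask <- function(nrow, ncol, center, axes, angle = 0) {
  r <- matrix(seq_len(nrow) - 1, nrow, ncol)
  c <- matrix(seq_len(ncol) - 1, nrow, ncol, byrow = TRUE)
  dr <- r - center[1L]; dc <- c - center[2L]
  u <- (dr * cos(angle) + dc * sin(angle)) / axes[1L]
  v <- (-dr * sin(angle) + dc * cos(angle)) / axes[2L]
  u * u + v * v <= 1
}

disk_mask <- function(nrow, ncol, center, radius) {
  ellipse_mask(nrow, ncol, center, c(radius, radius))
}

# Anatomy layout shared by generate_phantom and its validator. Skull and
# ventricle geometry are fixed fractions of the image size.
phantom_geometry <- function(spec) {
  n <- spec$image_size
  ctr <- c(n, n) / 2
  list(
    skull_outer = 0.48 * n,
    skull_inner = 0.44 * n,
    center = ctr,
    ventricles = list(
      list(center = ctr + c(-0.04, -0.09) * n,
           axes = c(0.10, 0.035) * n, angle = 0.35),
      list(center = ctr + c(-0.04, 0.09) * n,
           axes = c(0.10, 0.035) * n, angle = -0.35)
    )
  )
}

#' Generate a seeded synthetic MRI-like slice with ground truth
#'
#' Composes the noiseless piecewise-constant anatomy described by the spec
#' (air, brain disk, ventricle lobes, skull ring, tumor ellipse), then
#' passes it through [add_rician_noise()]. The returned ground truth holds
#' the exact rasterized tumor mask, its tight bounding box, and the class
#' label. Deterministic for a fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (numeric matrix in `[0, 1]`) and
#'   `truth` (list: `mask`, `box`, `label`).
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size = 128,
#'   tumor_center = c(80, 76), tumor_axes = c(12, 9)))
#' dim(ph$image)
#' ph$truth$box
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  geom <- phantom_geometry(spec)

  tumor <- ellipse_mask(n, n, spec$tumor_center, spec$tumor_axes,
                        spec$tumor_angle)
  if (!any(tumor)) stop("tumor ellipse rasterizes to an empty mask")

  brain <- disk_mask(n, n, geom$center, geom$skull_inner)
  skull <- disk_mask(n, n, geom$center, geom$skull_outer) & !brain
  vent <- matrix(FALSE, n, n)
  for (v in geom$ventricles) {
    vent <- vent | ellipse_mask(n, n, v$center, v$axes, v$angle)
  }
  vent <- vent & brain

  if (any(tumor & !brain)) {
    stop("configuration error: tumor ellipse extends outside the skull ring")
  }
  if (any(tumor & vent)) {
    stop("configuration error: tumor ellipse overlaps a ventricle distractor")
  }

  img <- matrix(spec$background_intensity, n, n)
  img[brain] <- spec$brain_intensity
  img[vent] <- spec$ventricle_intensity
  img[skull] <- spec$skull_intensity
  img[tumor] <- spec$tumor_intensity

  img <- add_rician_noise(img, spec$rician_sigma, spec$seed)

  list(image = img,
       truth = list(mask = tumor,
                    box = mask_to_bbox(tumor),
                    label = spec$class_label))
}

#' Add Rician magnitude noise to an image
#'
#' Magnitude MR images carry Rician noise: the acquired complex signal is
#' perturbed by independent Gaussian noise in the real and imaginary
#' channels, and the magnitude is taken. Each clean pixel `A` becomes
#' `sqrt((A + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)` independent; the
#' result is clipped back to `[0, 1]`. In the zero-signal limit this is
#' Rayleigh noise with mean `sigma * sqrt(pi / 2)`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param sigma Noise scale in intensity units; `>= 0`.
#' @param seed Integer seed; the draw is deterministic given `(image, sigma,
#'   seed)` and does not disturb the caller's RNG state.
#' @return Noisy matrix, same shape, values in `[0, 1]`.
#' @export
add_rician_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  d <- dim(image)
  with_seed(seed, {
    n1 <- matrix(stats::rnorm(length(image), sd = sigma), d[1L], d[2L])
    n2 <- matrix(stats::rnorm(length(image), sd = sigma), d[1L], d[2L])
    out <- sqrt((image + n1)^2 + n2^2)
    pmin(pmax(out, 0), 1)
  })
}

#' Surrogate localizer built from ground truth
#'
#' Stands in for a trained detector so the cascade runs end to end: takes
#' the true tumor box, expands it by `margin_frac` of its side per edge
#' (detector boxes enclose the object with context), then perturbs each of
#' the four edges independently by a uniform draw of up to `jitter_frac` of
#' the box side, and clips the result to the frame. The attached confidence
#' is `1 - mean(|draw fraction|)`, so an unjittered box has confidence 1.
#'
#' @param truth Ground-truth list from [generate_phantom()] (needs `mask`
#'   and `box`), or any list with a `box` and a `mask` giving the frame.
#' @param jitter_frac Maximum per-edge perturbation as a fraction of the box
#'   side; in `[0, 0.5]`.
#' @param margin_frac Symmetric expansion per side before jittering.
#' @param seed Integer seed.
#' @return A `bbox` with integer coordinates inside the frame.
#' @export
oracle_localizer <- function(truth, jitter_frac = 0, margin_frac = 0,
                             seed = 1L) {
  if (jitter_frac < 0 || jitter_frac > 0.5) {
    stop("jitter_frac must lie in [0, 0.5]")
  }
  box <- truth$box
  frame <- dim(truth$mask)
  h <- box$r1 - box$r0
  w <- box$c1 - box$c0
  r0 <- box$r0 - margin_frac * h; r1 <- box$r1 + margin_frac * h
  c0 <- box$c0 - margin_frac * w; c1 <- box$c1 + margin_frac * w
  d <- with_seed(seed, stats::runif(4L, -jitter_frac, jitter_frac))
  he <- r1 - r0; we <- c1 - c0
  r0 <- r0 + d[1L] * he; r1 <- r1 + d[2L] * he
  c0 <- c0 + d[3L] * we; c1 <- c1 + d[4L] * we
  r0 <- max(0, r0); c0 <- max(0, c0)
  r1 <- min(frame[1L], r1); c1 <- min(frame[2L], c1)
  if (r1 - r0 < 1 || c1 - c0 < 1) stop("jittered box is degenerate")
  conf <- 1 - mean(abs(d))
  snap_box(bbox(r0, c0, r1, c1, conf), frame)
}
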