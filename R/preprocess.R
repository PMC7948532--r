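#' Rescale image intensities to span [0, 1]
#'
#' Affine min-max normalization: the minimum maps to 0, the maximum to 1.
#' A constant image maps to all zeros (the affine map is undefined there).
#'
#' @param image Numeric matrix.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
rescale_intensity <- function(image) {
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(array(0, dim(image)))
  (image - lo) / (hi - lo)
}

#' Downsample an image by block averaging
#'
#' Anti-aliased integer-factor reduction: each output pixel is the mean of
#' its source block. Mirrors the resolution drop applied before
#' localization (512 to 128 by default).
#'
#' @param image Numeric matrix whose dimensions are integer multiples of
#'   `target_size`.
#' @param target_size Output side length in pixels.
#' @return `target_size x target_size` matrix; values stay in the input
#'   range.
#' @export
downsample <- function(image, target_size) {
  nr <- nrow(image); nc <- ncol(image)
  if (target_size > nr || target_size > nc) {
    stop("target_size exceeds the source size")
  }
  if (nr %% target_size != 0 || nc %% target_size != 0) {
    stop("downsampling factor must be an integer")
  }
  fr <- nr %/% target_size; fc <- nc %/% target_size
  g1 <- rep(seq_len(target_size), each = fr)
  tmp <- rowsum(image, g1) / fr                  # target x nc
  g2 <- rep(seq_len(target_size), each = fc)
  out <- t(rowsum(t(tmp), g2) / fc)              # target x target
  dimnames(out) <- NULL
  out
}

#' Contrast enhancement before contouring
#'
#' Two classical enhancement steps applied to the cropped box region before
#' the active contour runs: a percentile contrast stretch (2nd-98th
#' percentile mapped affinely onto `[0, 1]`, values outside clipped) and
#' 256-bin cumulative-histogram equalization. `"both"` stretches first and
#' then equalizes. Both maps are monotone, so pixel intensity ordering is
#' preserved (ties may merge); a constant crop is returned unchanged.
#'
#' @param image_crop Numeric matrix in `[0, 1]`.
#' @param method `"stretch"`, `"hist_eq"`, or `"both"` (default).
#' @param probs Lower/upper stretch percentiles as probabilities.
#' @param n_bins Number of equalization bins.
#' @return Enhanced crop in `[0, 1]`.
#' @export
enhance <- function(image_crop, method = c("both", "stretch", "hist_eq"),
                    probs = c(0.02, 0.98), n_bins = 256L) {
  method <- match.arg(method)
  if (length(image_crop) == 0L) stop("empty crop")
  out <- image_crop
  if (method %in% c("stretch", "both")) out <- stretch_contrast(out, probs)
  if (method %in% c("hist_eq", "both")) out <- hist_equalize(out, n_bins)
  out
}

stretch_contrast <- function(x, probs = c(0.02, 0.98)) {
  q <- stats::quantile(x, probs, names = FALSE, type = 7)
  if (q[2L] <= q[1L]) return(x)
  pmin(pmax((x - q[1L]) / (q[2L] - q[1L]), 0), 1)
}

hist_equalize <- function(x, n_bins = 256L) {
  if (max(x) == min(x)) return(x)   # degenerate histogram: identity
  bin <- pmin(floor(x * n_bins), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  cdf <- cumsum(counts) / length(x)
  out <- cdf[bin]
  dim(out) <- dim(x)
  out
}
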