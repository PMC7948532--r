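#' Axis-aligned bounding box
#'
#' Boxes are axis-aligned rectangles in pixel coordinates, using a 0-based,
#' half-open convention: a box `(r0, c0, r1, c1)` covers rows `r0 .. r1-1`
#' and columns `c0 .. c1-1` of the image grid, so its area is
#' `(r1-r0) * (c1-c0)`. A single pixel at `(r, c)` is the box
#' `(r, c, r+1, c+1)`. Coordinates may be fractional (anchor boxes are
#' continuous); boxes used for cropping are rounded to the pixel grid first.
#'
#' @param r0,c0 Top-left corner (inclusive).
#' @param r1,c1 Bottom-right corner (exclusive); must satisfy `r1 > r0`,
#'   `c1 > c0`.
#' @param confidence Detection confidence in `[0, 1]`.
#' @return An object of class `bbox`.
#' @examples
#' b <- bbox(10, 20, 50, 80)
#' bbox_area(b)
#' @export
bbox <- function(r0, c0, r1, c1, confidence = 1) {
  stopifnot(is.numeric(r0), is.numeric(c0), is.numeric(r1), is.numeric(c1))
  if (!(r1 > r0 && c1 > c0)) {
    stop("degenerate box: need r1 > r0 and c1 > c0")
  }
  if (confidence < 0 || confidence > 1) {
    stop("confidence must lie in [0, 1]")
  }
  structure(
    list(r0 = as.numeric(r0), c0 = as.numeric(c0),
         r1 = as.numeric(r1), c1 = as.numeric(c1),
         confidence = as.numeric(confidence)),
    class = "bbox"
  )
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox [%g,%g) x [%g,%g), conf %.3f>\n",
              x$r0, x$r1, x$c0, x$c1, x$confidence))
  invisible(x)
}

#' @rdname bbox
#' @param box A `bbox`.
#' @export
bbox_area <- function(box) {
  (box$r1 - box$r0) * (box$c1 - box$c0)
}

#' Intersection over union of two boxes
#'
#' Area of overlap divided by area of union, in `[0, 1]`. Symmetric in its
#' arguments; equals 1 exactly when the boxes coincide and 0 when they are
#' disjoint. This is the anchor-labeling criterion used by region proposal
#' networks.
#'
#' @param a,b `bbox` objects.
#' @return Scalar IoU.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  ir <- min(a$r1, b$r1) - max(a$r0, b$r0)
  ic <- min(a$c1, b$c1) - max(a$c0, b$c0)
  inter <- max(0, ir) * max(0, ic)
  union <- bbox_area(a) + bbox_area(b) - inter
  inter / union
}

#' Tight bounding box of a binary mask
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return The tightest `bbox` (half-open, 0-based) containing all
#'   foreground pixels.
#' @export
mask_to_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground pixels")
  # arr.ind is 1-based; half-open 0-based box
  bbox(min(idx[, 1L]) - 1L, min(idx[, 2L]) - 1L,
       max(idx[, 1L]), max(idx[, 2L]))
}

#' Map a box between the localization and segmentation resolutions
#'
#' Localization runs on a downsampled frame (128 pixels by default); the
#' contour runs at acquisition resolution (512). Mapping "up" multiplies
#' every coordinate by the integer scale factor and is exactly invertible;
#' mapping "down" divides, flooring the near corner and ceiling the far one
#' so the mapped box never loses coverage.
#'
#' @param box A `bbox` in the source frame.
#' @param res `resolution_pair()` giving the two frame sizes.
#' @param direction `"up"` (low to high, the default) or `"down"`.
#' @return The mapped `bbox`; confidence is preserved.
#' @export
map_box <- function(box, res = resolution_pair(), direction = c("up", "down")) {
  direction <- match.arg(direction)
  f <- res$high_size / res$low_size
  if (direction == "up") {
    frame <- res$low_size
    if (box$r0 < 0 || box$c0 < 0 || box$r1 > frame || box$c1 > frame) {
      stop("box lies outside the low-resolution frame")
    }
    bbox(box$r0 * f, box$c0 * f, box$r1 * f, box$c1 * f, box$confidence)
  } else {
    frame <- res$high_size
    if (box$r0 < 0 || box$c0 < 0 || box$r1 > frame || box$c1 > frame) {
      stop("box lies outside the high-resolution frame")
    }
    bbox(floor(box$r0 / f), floor(box$c0 / f),
         ceiling(box$r1 / f), ceiling(box$c1 / f), box$confidence)
  }
}

#' Low/high resolution frame pair
#'
#' @param low_size Side of the localization frame in pixels (default 128).
#' @param high_size Side of the segmentation frame in pixels (default 512);
#'   must be an integer multiple of `low_size`.
#' @export
resolution_pair <- function(low_size = 128L, high_size = 512L) {
  if (high_size %% low_size != 0) {
    stop("high_size must be an integer multiple of low_size")
  }
  structure(list(low_size = as.integer(low_size),
                 high_size = as.integer(high_size)),
            class = "resolution_pair")
}

#' Extract the sub-image covered by a box
#'
#' @param image Numeric matrix.
#' @param box Integer-coordinate `bbox` lying inside the image.
#' @return The crop, a matrix of size `(r1-r0) x (c1-c0)`.
#' @export
crop_to_box <- function(image, box) {
  d <- dim(image)
  if (box$r0 < 0 || box$c0 < 0 || box$r1 > d[1L] || box$c1 > d[2L]) {
    stop("box lies outside the image")
  }
  image[(box$r0 + 1):box$r1, (box$c0 + 1):box$c1, drop = FALSE]
}

#' Paste a crop back into a full frame at a box position
#'
#' Inverse of [crop_to_box()]: writes `crop` into `frame` over the box
#' extent and leaves every other pixel untouched.
#'
#' @param frame Matrix to write into.
#' @param crop Matrix whose dimensions equal the box extent.
#' @param box Target `bbox`.
#' @export
paste_at_box <- function(frame, crop, box) {
  d <- dim(frame)
  if (box$r0 < 0 || box$c0 < 0 || box$r1 > d[1L] || box$c1 > d[2L]) {
    stop("box lies outside the frame")
  }
  if (!all(dim(crop) == c(box$r1 - box$r0, box$c1 - box$c0))) {
    stop("crop dimensions do not match the box extent")
  }
  frame[(box$r0 + 1):box$r1, (box$c0 + 1):box$c1] <- crop
  frame
}

# Round a (possibly fractional) box to the pixel grid, clipped to the frame.
snap_box <- function(box, frame_dim) {
  r0 <- max(0, floor(box$r0)); c0 <- max(0, floor(box$c0))
  r1 <- min(frame_dim[1L], ceiling(box$r1))
  c1 <- min(frame_dim[2L], ceiling(box$c1))
  if (r1 <= r0 || c1 <= c0) stop("box degenerate after snapping to frame")
  bbox(r0, c0, r1, c1, box$confidence)
}
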