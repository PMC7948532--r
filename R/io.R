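#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel files are collapsed to grayscale by channel averaging;
#' values are returned as a numeric matrix in `[0, 1]` (integer files are
#' divided by their bit-depth maximum by the underlying readers).
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext))
  if (length(dim(x)) == 3L) x <- apply(x, c(1L, 2L), mean)
  x
}

#' @rdname read_image
#' @param image Numeric matrix in `[0, 1]`.
#' @param bits TIFF bit depth (8 or 16; default 16).
#' @export
write_image <- function(image, path, bits = 16L) {
  ext <- tolower(tools::file_ext(path))
  image <- pmin(pmax(image, 0), 1)
  switch(ext,
         png = png::writePNG(image, path),
         tif = ,
         tiff = tiff::writeTIFF(image, path, bits.per.sample = bits),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Read / write a binary mask as a 0/255 PNG
#'
#' @param path PNG file path.
#' @return `read_mask()`: logical matrix (pixels above 0.5 are
#'   foreground).
#' @export
read_mask <- function(path) {
  read_image(path) > 0.5
}

#' @rdname read_mask
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

bbox_to_list <- function(box) {
  list(r0 = box$r0, c0 = box$c0, r1 = box$r1, c1 = box$c1,
       confidence = box$confidence)
}

list_to_bbox <- function(x) {
  bbox(x$r0, x$c0, x$r1, x$c1, x$confidence)
}
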