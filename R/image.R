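#' Image containers
#'
#' The pipeline's working representation of a single-plane image is a plain
#' numeric matrix (rows = image rows, columns = image columns) holding
#' floating-point intensities on the 0--255 scale.  Quantization to 8-bit
#' integers happens only when an image is written to disk.  A color image is
#' a list of three such planes with class \code{"rgb_image"}; binary masks
#' are logical matrices of the same shape as the image they annotate.
#'
#' @param red,green,blue numeric matrices of identical dimensions.
#' @return \code{rgb_image()} returns a list with components \code{red},
#'   \code{green}, \code{blue} and class \code{"rgb_image"}.
#' @export
rgb_image <- function(red, green, blue) {
  red <- as_image(red); green <- as_image(green); blue <- as_image(blue)
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue)))
    stop("rgb_image: the three planes must share identical dimensions")
  structure(list(red = red, green = green, blue = blue), class = "rgb_image")
}

#' @rdname rgb_image
#' @param x object to test / coerce.
#' @export
is_rgb_image <- function(x) inherits(x, "rgb_image")

#' @rdname rgb_image
#' @export
as_image <- function(x) {
  if (is_rgb_image(x)) stop("as_image: got an rgb_image; pick a plane first")
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("as_image: values must be numeric")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("as_image: image must be at least 1x1")
  if (!all(is.finite(x))) stop("as_image: all pixel values must be finite")
  storage.mode(x) <- "double"
  x
}

# internal: shape check shared by binary ops
check_same_shape <- function(x, y, what = "images") {
  if (!identical(dim(x), dim(y)))
    stop(sprintf("%s must have identical dimensions (%s vs %s)", what,
                 paste(dim(x), collapse = "x"), paste(dim(y), collapse = "x")))
  invisible(TRUE)
}

#' Rescale an image to the full 8-bit range
#'
#' Affine map sending the image minimum to 0 and maximum to 255.  A constant
#' image (zero dynamic range) maps to all zeros rather than erroring, so that
#' batch runs survive degenerate inputs.
#'
#' @param img numeric matrix on any scale.
#' @return numeric matrix with minimum 0 and maximum 255 (all zeros if the
#'   input was constant).
#' @export
rescale_to_8bit <- function(img) {
  img <- as_image(img)
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(array(0, dim(img)))
  # clamp away float round-off so the contract min >= 0, max <= 255 is exact
  clip255((img - lo) * (255 / (hi - lo)))
}

# internal: clip to [0,255]
clip255 <- function(img) pmin(pmax(img, 0), 255)

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical matrices of identical shape.
#' @return 2|A n B| / (|A| + |B|); defined as 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  check_same_shape(a, b, "masks")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
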