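#' Structuring elements for flat grayscale morphology
#'
#' @param radius disk radius in pixels (footprint is \code{(2r+1)^2} with
#'   \code{x^2 + y^2 <= r^2}).
#' @return logical matrix with odd dimensions and a true central anchor,
#'   of class \code{"struct_elem"}.
#' @export
se_disk <- function(radius) {
  radius <- as.integer(radius)
  stopifnot(radius >= 1)
  d <- 2L * radius + 1L
  off <- seq_len(d) - radius - 1L
  fp <- outer(off^2, off^2, "+") <= radius^2
  structure(fp, class = c("struct_elem", class(fp)))
}

#' @rdname se_disk
#' @param size odd side length of a square footprint.
#' @export
se_square <- function(size) {
  size <- as.integer(size)
  stopifnot(size >= 1, size %% 2 == 1)
  structure(matrix(TRUE, size, size), class = c("struct_elem", "matrix"))
}

# internal: accept struct_elem or any logical matrix with odd dims + true anchor
check_se <- function(b) {
  b <- as.matrix(b)
  if (!is.logical(b)) storage.mode(b) <- "logical"
  if (nrow(b) %% 2 == 0 || ncol(b) %% 2 == 0)
    stop("structuring element must have odd height and width")
  if (!b[nrow(b) %/% 2 + 1, ncol(b) %/% 2 + 1])
    stop("structuring element anchor (central pixel) must be true")
  b
}

# default SE for background uniformity: flat disk, radius 15 px at 1024 px
# image extent, scaled proportionally (structures of interest are much larger
# than noise speckle)
default_se <- function(img) {
  se_disk(max(3L, round(15 * max(dim(img)) / 1024)))
}

#' Morphological primitives on grayscale images
#'
#' Flat erosion, dilation, opening and closing with an arbitrary binary
#' footprint, replicate (clamp-to-edge) border handling.
#'
#' @param f numeric matrix (intensity image).
#' @param b structuring element (see [se_disk]); logical matrix with odd
#'   dimensions and a true central anchor.
#' @return numeric matrix of the same shape.
#' @export
erode <- function(f, b) cpp_erode(as_image(f), check_se(b))

#' @rdname erode
#' @export
dilate <- function(f, b) cpp_dilate(as_image(f), check_se(b))

#' @rdname erode
#' @export
opening <- function(f, b) {
  b <- check_se(b)
  cpp_dilate(cpp_erode(as_image(f), b), b)
}

#' @rdname erode
#' @export
closing <- function(f, b) {
  b <- check_se(b)
  cpp_erode(cpp_dilate(as_image(f), b), b)
}

#' Hat transforms and background uniformity
#'
#' The bottom-hat transform \code{closing(f) - f} extracts dark structures
#' smaller than the structuring element (noise, thin dark detail); the
#' top-hat transform \code{f - opening(f)} extracts the corresponding bright
#' structures.  Both are non-negative everywhere by the extensivity of
#' closing / anti-extensivity of opening.
#'
#' \code{uniformize()} composes them into the classic morphological contrast
#' enhancement \code{f + top_hat(f) - bottom_hat(f)} — bright small-scale
#' structure is amplified, dark small-scale structure (background noise) is
#' suppressed — and rescales the result to \eqn{[0, 255]}.
#'
#' @param f numeric matrix on the 0--255 scale.
#' @param b structuring element; defaults to a flat disk whose radius is 15
#'   px at 1024-px image extent, scaled proportionally.
#' @return numeric matrix: non-negative hat response, or (for
#'   \code{uniformize}) an enhanced image on \eqn{[0, 255]}.
#' @export
bottom_hat <- function(f, b = default_se(f)) {
  f <- as_image(f)
  closing(f, b) - f
}

#' @rdname bottom_hat
#' @export
top_hat <- function(f, b = default_se(f)) {
  f <- as_image(f)
  f - opening(f, b)
}

#' @rdname bottom_hat
#' @export
uniformize <- function(f, b = default_se(f)) {
  f <- as_image(f)
  rescale_to_8bit(f + top_hat(f, b) - bottom_hat(f, b))
}
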