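#' Detect mammogram orientation (chest-wall side)
#'
#' The breast is anchored to the chest-wall edge of the frame, so the image
#' half (left vs right columns) with the greater mean intensity identifies
#' that side.  An exact tie returns \code{"left"} with a warning.
#'
#' @param img numeric matrix on the 0--255 scale.
#' @return \code{"left"} or \code{"right"}.
#' @export
detect_orientation <- function(img) {
  img <- as_image(img)
  w <- ncol(img)
  half <- w %/% 2
  ml <- mean(img[, seq_len(half)])
  mr <- mean(img[, (w - half + 1L):w])
  if (ml == mr) {
    warning("detect_orientation: exact tie between halves; returning 'left'")
    return("left")
  }
  if (ml > mr) "left" else "right"
}

#' Region-growing parameters for pectoral muscle removal
#'
#' @param intensity_tolerance maximum absolute difference from the running
#'   region mean for a neighbor to be accepted (intensity units).
#' @param connectivity 4 or 8.
#' @param max_region_fraction growth stops once the region reaches this
#'   fraction of the image area.
#' @param seed_offset seed placement, in pixels inward from the detected
#'   top chest-wall corner.
#' @param floor_intensity a seed darker than this is considered background
#'   and rejected with an error.
#' @return list of class \code{"region_grow_params"}.
#' @export
region_grow_params <- function(intensity_tolerance = 25, connectivity = 8,
                               max_region_fraction = 0.35, seed_offset = 10,
                               floor_intensity = 10) {
  stopifnot(intensity_tolerance > 0,
            connectivity %in% c(4, 8),
            max_region_fraction > 0, max_region_fraction <= 1,
            seed_offset >= 0)
  structure(list(intensity_tolerance = intensity_tolerance,
                 connectivity = as.integer(connectivity),
                 max_region_fraction = max_region_fraction,
                 seed_offset = as.integer(seed_offset),
                 floor_intensity = floor_intensity),
            class = "region_grow_params")
}

#' Grow the pectoral muscle region from an automatic corner seed
#'
#' On MLO views the pectoral muscle occupies the top corner on the chest-wall
#' side.  The seed is placed \code{seed_offset} pixels inward from that
#' corner (orientation detected automatically unless given), and the region
#' grows by repeatedly accepting connected neighbors whose intensity differs
#' from the \emph{running region mean} by at most the tolerance.  The
#' adaptive mean follows the muscle's internal intensity gradient better
#' than a fixed seed-value test.  Growth halts when no candidate qualifies
#' or when the region reaches \code{max_region_fraction} of the image area.
#'
#' @param img numeric matrix on the 0--255 scale.
#' @param params a [region_grow_params].
#' @param orientation \code{"left"}, \code{"right"}, or \code{NULL} to
#'   auto-detect via [detect_orientation].
#' @return logical mask of the grown region.
#' @export
grow_pectoral <- function(img, params = region_grow_params(),
                          orientation = NULL) {
  img <- as_image(img)
  stopifnot(inherits(params, "region_grow_params"))
  if (is.null(orientation)) orientation <- detect_orientation(img)
  h <- nrow(img); w <- ncol(img)
  r0 <- min(params$seed_offset + 1L, h)
  c0 <- if (orientation == "left") min(params$seed_offset + 1L, w)
        else max(w - params$seed_offset, 1L)
  if (img[r0, c0] < params$floor_intensity)
    stop("grow_pectoral: seed pixel at (", r0, ",", c0, ") has background ",
         "intensity ", img[r0, c0], "; try a different seed_offset")
  cap <- max(1L, as.integer(floor(params$max_region_fraction * h * w)))
  res <- cpp_region_grow(img, r0 - 1L, c0 - 1L, params$intensity_tolerance,
                         params$connectivity, cap)
  res$mask
}

#' Zero out a masked region
#'
#' Pixels under the mask are set to 0 (background); all others are unchanged.
#' The raster geometry is preserved (no cropping) so downstream metrics keep
#' a common frame.
#'
#' @param img numeric matrix.
#' @param mask logical matrix of the same shape.
#' @return numeric matrix with the masked region zeroed.
#' @export
remove_pectoral <- function(img, mask) {
  img <- as_image(img)
  check_same_shape(img, mask, "image and mask")
  img[mask] <- 0
  img
}
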