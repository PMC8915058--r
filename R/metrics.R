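# Enhancement quality metrics: MSE/PSNR, log-contrast, EME.

# peak (dynamic range) constant for 8-bit images: L = 2^8 - 1
PSNR_PEAK_8BIT <- 2^8 - 1

#' 8-bit PSNR dynamic-range constant
#'
#' The maximum pixel value of an 8-bit image, \eqn{L = 2^8 - 1 = 255}, used
#' as the peak in [psnr].  Exposed for readback so reports can state the
#' constant actually used.
#'
#' @return 255.
#' @export
psnr_peak <- function() PSNR_PEAK_8BIT

#' Mean squared error between two images
#'
#' @param x,y numeric matrices of identical shape.
#' @return mean of squared per-pixel differences.
#' @export
mse <- function(x, y) {
  x <- as_image(x); y <- as_image(y)
  check_same_shape(x, y)
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' Two variants are provided.  \code{"as_printed"} (default) computes
#' \eqn{10 \log_{10}((L-1)/\mathrm{MSE})} with \eqn{L = 255}, the formula as
#' published for this pipeline; \code{"standard"} computes the universal
#' \eqn{10 \log_{10}(L^2/\mathrm{MSE})}.  The printed form is nonstandard
#' (the peak enters linearly rather than squared) and yields much smaller
#' numbers; both are kept so results can be compared on either convention.
#'
#' @param x,y reference and test image, identical shapes, 0--255 scale.
#' @param variant \code{"as_printed"} or \code{"standard"}.
#' @return PSNR in dB, or \code{NA} with a warning for identical images
#'   (MSE = 0, infinite PSNR).
#' @export
psnr <- function(x, y, variant = c("as_printed", "standard")) {
  variant <- match.arg(variant)
  m <- mse(x, y)
  if (m == 0) {
    warning("psnr: images identical (MSE = 0); PSNR undefined")
    return(NA_real_)
  }
  L <- PSNR_PEAK_8BIT
  if (variant == "as_printed") 10 * log10((L - 1) / m)
  else 10 * log10(L^2 / m)
}

#' Global image contrast in decibels
#'
#' The contrast statistic is the population variance of the intensities,
#' \eqn{C = \mathrm{mean}(Y^2) - \mathrm{mean}(Y)^2}, reported on a log
#' scale as \eqn{10 \log_{10} C} dB.  Higher is better-contrasted.
#'
#' @param y numeric matrix.
#' @return contrast in dB, or \code{NA} with a warning for a constant image.
#' @export
contrast_db <- function(y) {
  y <- as_image(y)
  C <- mean(y^2) - mean(y)^2
  if (C <= 0) {
    warning("contrast_db: zero variance; contrast undefined")
    return(NA_real_)
  }
  10 * log10(C)
}

#' Effective measure of enhancement (EME)
#'
#' Partitions the image into a \code{k1 x k2} grid of blocks (\code{k1}
#' horizontal, i.e. across columns; \code{k2} vertical; remainder pixels are
#' absorbed by the last row/column of blocks) and averages
#' \eqn{20 \log_{10}(I_{max}/I_{min})} over blocks.  To keep the measure
#' finite on blocks touching zero, both extrema are floored at \code{eps}
#' (default 1 intensity unit).
#'
#' @param y numeric matrix on the 0--255 scale.
#' @param k1 number of blocks across the image width.
#' @param k2 number of blocks down the image height.
#' @param eps floor applied to block extrema.
#' @return dimensionless EME value (\eqn{\ge 0}).
#' @export
eme <- function(y, k1 = 8L, k2 = 8L, eps = 1) {
  y <- as_image(y)
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (k1 < 1L || k2 < 1L) stop("eme: k1 and k2 must be >= 1")
  if (k1 > ncol(y) || k2 > nrow(y))
    stop("eme: more blocks than pixels along an axis")
  cb <- block_bounds(ncol(y), k1)
  rb <- block_bounds(nrow(y), k2)
  total <- 0
  for (l in seq_len(k2)) {
    for (k in seq_len(k1)) {
      blk <- y[rb$from[l]:rb$to[l], cb$from[k]:cb$to[k]]
      total <- total + 20 * log10(max(max(blk), eps) / max(min(blk), eps))
    }
  }
  total / (k1 * k2)
}

# near-equal partition of n pixels into k blocks, remainder to the last block
block_bounds <- function(n, k) {
  size <- n %/% k
  from <- (seq_len(k) - 1L) * size + 1L
  to <- c(from[-1L] - 1L, n)
  list(from = from, to = to)
}

#' Assemble a metrics report for one (original, enhanced) pair
#'
#' @param original,enhanced numeric matrices of identical shape, 0--255.
#' @param k1,k2 EME block grid (see [eme]).
#' @param psnr_variant PSNR convention (see [psnr]).
#' @return one-row \code{data.frame} with columns \code{psnr_db},
#'   \code{contrast_db_original}, \code{contrast_db_enhanced},
#'   \code{eme_original}, \code{eme_enhanced}, \code{psnr_variant},
#'   \code{k1}, \code{k2}.  Undefined metrics are \code{NA}, never an error,
#'   so batch runs survive degenerate pairs.
#' @export
metrics_report <- function(original, enhanced, k1 = 8L, k2 = 8L,
                           psnr_variant = c("as_printed", "standard")) {
  psnr_variant <- match.arg(psnr_variant)
  safely_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  data.frame(
    psnr_db = safely_na(psnr(original, enhanced, psnr_variant)),
    contrast_db_original = safely_na(contrast_db(original)),
    contrast_db_enhanced = safely_na(contrast_db(enhanced)),
    eme_original = safely_na(eme(original, k1, k2)),
    eme_enhanced = safely_na(eme(enhanced, k1, k2)),
    psnr_variant = psnr_variant, k1 = k1, k2 = k2,
    stringsAsFactors = FALSE)
}
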