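#' RGB to YCbCr (full-range BT.601)
#'
#' Separates luminance from chrominance before the PCA fusion.  Full-range
#' ITU-R BT.601 is the conventional transform for JPEG-pipeline imagery:
#' \deqn{Y = 0.299 R + 0.587 G + 0.114 B}
#' with Cb and Cr offset by 128 and clipped to \eqn{[0, 255]}.  An achromatic
#' pixel \code{(v,v,v)} maps to \code{Y = v, Cb = Cr = 128}.
#'
#' @param img an [rgb_image] on the 0--255 scale.
#' @return list with planes \code{Y}, \code{Cb}, \code{Cr}.
#' @export
to_ycbcr <- function(img) {
  stopifnot(is_rgb_image(img))
  r <- img$red; g <- img$green; b <- img$blue
  y  <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  cr <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  list(Y = y, Cb = clip255(cb), Cr = clip255(cr))
}

#' PCA fusion of three channels into one grayscale image
#'
#' Stacks the YCbCr planes into a \eqn{3 \times n} matrix, mean-centers each
#' row, eigendecomposes the \eqn{3 \times 3} covariance (1/n normalization),
#' projects the centered data onto each eigenvector, and combines the three
#' projections with weights proportional to the eigenvalues,
#' \eqn{w_i = \lambda_i / (\lambda_1 + \lambda_2 + \lambda_3)} with
#' \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}.  The first projection
#' dominates whenever \eqn{\lambda_1} is much larger than the others; for
#' achromatic input (R = G = B) the covariance has rank one in Y only and the
#' output reduces to the rescaled common channel.  The combined image is
#' rescaled to \eqn{[0, 255]}.
#'
#' Eigenvectors are defined only up to sign; each is oriented so that its
#' largest-magnitude component is positive (ties broken toward the first
#' component), making the map deterministic.
#'
#' @param img an [rgb_image] on the 0--255 scale with at least 2 pixels.
#' @return numeric matrix on \eqn{[0, 255]}.
#' @export
pca_gray <- function(img) {
  stopifnot(is_rgb_image(img))
  ycc <- to_ycbcr(img)
  dm <- dim(ycc$Y)
  n <- prod(dm)
  if (n < 2) stop("pca_gray: image must have at least 2 pixels")
  X <- rbind(as.vector(ycc$Y), as.vector(ycc$Cb), as.vector(ycc$Cr))
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / n
  if (sum(diag(C)) < .Machine$double.eps * 255^2) {
    warning("pca_gray: all channels constant; returning all-zero image")
    return(array(0, dm))
  }
  e <- eigen(C, symmetric = TRUE)   # eigenvalues already sorted descending
  V <- apply(e$vectors, 2, fix_eigvec_sign)
  lam <- pmax(e$values, 0)
  w <- lam / sum(lam)
  g <- as.vector(crossprod(V, X) * w)  # recycles w down the 3 rows
  g <- colSums(matrix(g, nrow = 3))
  rescale_to_8bit(array(g, dm))
}

# orient an eigenvector so its largest-|.| component is positive; ties toward
# the first component
fix_eigvec_sign <- function(v) {
  a <- abs(v)
  i <- which(a == max(a))[1]
  if (v[i] < 0) -v else v
}
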