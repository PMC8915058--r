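# Coherence stage: Laplacian-of-Gaussian normalization followed by
# coherence-enhancing (orientation-driven) anisotropic diffusion with an
# entropy-based stopping rule.

# 1-D Gaussian kernel, truncated at trunc*sigma, normalized to sum 1
gauss_kernel1d <- function(sigma, trunc = 4) {
  r <- max(1L, ceiling(trunc * sigma))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D Gaussian-derivative kernel for correlation semantics, normalized so the
# response on a unit ramp is exactly 1
dgauss_kernel1d <- function(sigma, trunc = 4) {
  r <- max(1L, ceiling(trunc * sigma))
  x <- -r:r
  k <- x * exp(-x^2 / (2 * sigma^2))
  k / sum(k * x)
}

# separable Gaussian smoothing, replicate borders
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel1d(sigma)
  cpp_filter2(cpp_filter2(img, matrix(k, ncol = 1)), matrix(k, nrow = 1))
}

# Gaussian-derivative gradients; x runs along columns, y down rows
gauss_gradients <- function(img, sigma) {
  g <- matrix(gauss_kernel1d(sigma), ncol = 1)
  d <- matrix(dgauss_kernel1d(sigma), nrow = 1)
  list(gx = cpp_filter2(cpp_filter2(img, g), d),
       gy = cpp_filter2(cpp_filter2(img, t(d)), t(g)))
}

#' Laplacian-of-Gaussian normalization
#'
#' Convolves with the LoG kernel
#' \deqn{(x^2 + y^2 - 2\sigma^2)/\sigma^4 \exp(-(x^2+y^2)/2\sigma^2)}
#' truncated at \eqn{4\sigma} and re-centered to exact zero sum after
#' truncation (so flat regions produce an identically zero response).  The
#' response is an intensity-normalized band-pass image that equalizes
#' structure across differently exposed mammograms.
#'
#' @param img numeric matrix on the 0--255 scale.
#' @param sigma kernel scale in pixels (> 0).
#' @param rescale if \code{TRUE} (default) the response is rescaled to
#'   \eqn{[0, 255]}; \code{FALSE} returns the raw response.
#' @return numeric matrix.
#' @export
log_filter <- function(img, sigma = 2, rescale = TRUE) {
  img <- as_image(img)
  stopifnot(sigma > 0)
  ker <- log_kernel(sigma)
  out <- cpp_filter2(img, ker)
  if (rescale) rescale_to_8bit(out) else out
}

# LoG kernel, zero-sum enforced after truncation
log_kernel <- function(sigma, trunc = 4) {
  r <- max(1L, ceiling(trunc * sigma))
  x <- -r:r
  r2 <- outer(x^2, x^2, "+")
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

#' Structure tensor (second-moment matrix) field
#'
#' Gaussian-derivative gradients at \code{gradient_sigma}; the per-pixel
#' outer product of the gradient is then smoothed componentwise at
#' \code{tensor_sigma}.  The dominant angle is the direction of the
#' principal eigenvector (the locally dominant gradient direction), wrapped
#' to \eqn{[-\pi/2, \pi/2)}; a zero tensor gets angle 0 by convention.
#'
#' @param img numeric matrix.
#' @param gradient_sigma,tensor_sigma scales in pixels (> 0).
#' @return list of class \code{"orientation_field"} with per-pixel matrices
#'   \code{J11}, \code{J12}, \code{J22} and \code{angle}.
#' @export
structure_tensor <- function(img, gradient_sigma = 1, tensor_sigma = 3) {
  img <- as_image(img)
  stopifnot(gradient_sigma > 0, tensor_sigma > 0)
  gr <- gauss_gradients(img, gradient_sigma)
  J11 <- gauss_smooth(gr$gx * gr$gx, tensor_sigma)
  J12 <- gauss_smooth(gr$gx * gr$gy, tensor_sigma)
  J22 <- gauss_smooth(gr$gy * gr$gy, tensor_sigma)
  ang <- 0.5 * atan2(2 * J12, J11 - J22)
  # flat regions (tensor energy at round-off level): angle 0 by convention
  ang[J11 + J22 <= 1e-10] <- 0
  ang[ang >= pi / 2] <- ang[ang >= pi / 2] - pi
  ang[ang < -pi / 2] <- ang[ang < -pi / 2] + pi
  structure(list(J11 = J11, J12 = J12, J22 = J22, angle = ang),
            class = "orientation_field")
}

#' Diffusion tensor from an orientation field
#'
#' Coherence-enhancing mapping: the diffusion tensor shares the structure
#' tensor's eigenvectors; diffusivity \emph{across} the local structure (the
#' dominant-gradient direction) is pinned at the minimum \code{alpha}, while
#' diffusivity \emph{along} the structure is
#' \deqn{\alpha + (1-\alpha)\exp(-C / (\mu_1-\mu_2)^2)}
#' when the tensor eigenvalues differ, and \eqn{\alpha} otherwise: flat
#' regions diffuse isotropically and weakly, strongly oriented regions
#' diffuse along their orientation with diffusivity approaching 1.
#'
#' @param field an \code{orientation_field} from [structure_tensor].
#' @param alpha minimum diffusivity in (0, 1).
#' @param coherence_scale \eqn{C} above, in squared units of the tensor
#'   eigenvalue difference (intensity^4 on the 0--255 scale).
#' @return list with per-pixel diffusion-tensor components \code{D11},
#'   \code{D12}, \code{D22}.
#' @export
diffusion_tensor <- function(field, alpha = 0.05, coherence_scale = 1e6) {
  stopifnot(inherits(field, "orientation_field"),
            alpha > 0, alpha < 1, coherence_scale > 0)
  J11 <- field$J11; J12 <- field$J12; J22 <- field$J22
  tr <- J11 + J22
  disc <- sqrt(pmax((J11 - J22)^2 + 4 * J12^2, 0))
  mu1 <- (tr + disc) / 2
  mu2 <- (tr - disc) / 2
  lam2 <- ifelse(mu1 > mu2,
                 alpha + (1 - alpha) * exp(-coherence_scale / (mu1 - mu2)^2),
                 alpha)
  # principal eigenvector (cos t, sin t) of J; D = alpha v1 v1' + lam2 v2 v2'
  t1 <- field$angle
  ct <- cos(t1); st <- sin(t1)
  list(D11 = alpha * ct^2 + lam2 * st^2,
       D12 = (alpha - lam2) * ct * st,
       D22 = alpha * st^2 + lam2 * ct^2)
}

#' Diffusion configuration
#'
#' @param dt explicit-scheme time step, in (0, 0.25] for stability.
#' @param gradient_sigma,tensor_sigma structure-tensor scales (pixels).
#' @param alpha minimum diffusivity in (0, 1).
#' @param coherence_scale coherence sensitivity (see [diffusion_tensor]).
#' @param max_iters iteration cap (>= 1).
#' @param entropy_tol stopping threshold on the per-iteration change of the
#'   256-bin histogram Shannon entropy, in bits.
#' @return list of class \code{"diffusion_config"}.
#' @export
diffusion_config <- function(dt = 0.2, gradient_sigma = 1, tensor_sigma = 3,
                             alpha = 0.05, coherence_scale = 1e6,
                             max_iters = 50, entropy_tol = 1e-3) {
  stopifnot(dt > 0, dt <= 0.25, max_iters >= 1, entropy_tol >= 0)
  structure(list(dt = dt, gradient_sigma = gradient_sigma,
                 tensor_sigma = tensor_sigma, alpha = alpha,
                 coherence_scale = coherence_scale,
                 max_iters = as.integer(max_iters),
                 entropy_tol = entropy_tol),
            class = "diffusion_config")
}

# divergence-form update div(D grad I): half-point fluxes for the diagonal
# terms (reduces exactly to the 5-point Laplacian when D = I), central
# differences for the mixed terms; replicate (Neumann) boundaries
diffusion_step_rhs <- function(I, D) {
  h <- nrow(I); w <- ncol(I)
  shl <- function(m) m[, c(2:w, w), drop = FALSE]   # value at col+1
  shr <- function(m) m[, c(1, 1:(w - 1)), drop = FALSE]
  shu <- function(m) m[c(2:h, h), , drop = FALSE]   # value at row+1
  shd <- function(m) m[c(1, 1:(h - 1)), , drop = FALSE]
  a <- D$D11; b <- D$D12; c_ <- D$D22
  # d/dx (a Ix): fluxes at column half-points vanish at the replicate edge
  tx <- (shl(a) + a) / 2 * (shl(I) - I) - (a + shr(a)) / 2 * (I - shr(I))
  ty <- (shu(c_) + c_) / 2 * (shu(I) - I) - (c_ + shd(c_)) / 2 * (I - shd(I))
  Ix <- (shl(I) - shr(I)) / 2
  Iy <- (shu(I) - shd(I)) / 2
  bIy <- b * Iy
  bIx <- b * Ix
  txy <- (shl(bIy) - shr(bIy)) / 2
  tyx <- (shu(bIx) - shd(bIx)) / 2
  tx + ty + txy + tyx
}

# Shannon entropy (bits) of the 256-bin histogram of a [0,255]-clipped image
histogram_entropy <- function(img) {
  counts <- tabulate(pmin(pmax(floor(img), 0), 255) + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(img)
  -sum(p * log2(p))
}

#' Coherence-enhancing anisotropic diffusion
#'
#' Explicit iteration \eqn{I \leftarrow I + \Delta t\, \mathrm{div}(D \nabla I)}
#' with homogeneous Neumann (replicate) boundaries.  The diffusion tensor
#' \eqn{D} is recomputed from the current image every iteration
#' ([structure_tensor] then [diffusion_tensor]), so smoothing follows the
#' evolving local orientation.  After each step the Shannon entropy of the
#' 256-bin intensity histogram is computed; iteration stops when the entropy
#' changes by less than \code{entropy_tol} bits or \code{max_iters} is
#' reached.  The returned image is clipped to \eqn{[0, 255]}.
#'
#' @param img numeric matrix on the 0--255 scale.
#' @param cfg a [diffusion_config].
#' @return list with \code{image} (diffused, clipped), \code{iterations}
#'   (number of update steps run) and \code{entropy_trace} (entropy after
#'   each step, preceded by the input's entropy).
#' @export
diffuse <- function(img, cfg = diffusion_config()) {
  I <- as_image(img)
  stopifnot(inherits(cfg, "diffusion_config"))
  trace <- histogram_entropy(clip255(I))
  iters <- 0L
  for (t in seq_len(cfg$max_iters)) {
    J <- structure_tensor(I, cfg$gradient_sigma, cfg$tensor_sigma)
    D <- diffusion_tensor(J, cfg$alpha, cfg$coherence_scale)
    I <- I + cfg$dt * diffusion_step_rhs(I, D)
    if (any(!is.finite(I)))
      stop("diffuse: non-finite values at iteration ", t,
           "; reduce dt or check the input scale")
    iters <- t
    trace <- c(trace, histogram_entropy(clip255(I)))
    if (abs(trace[t + 1] - trace[t]) < cfg$entropy_tol) break
  }
  list(image = clip255(I), iterations = iters, entropy_trace = trace)
}
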