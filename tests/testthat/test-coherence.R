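test_that("LoG kernel is zero-sum and reproduces the analytic impulse response", {
  k <- mammoenhance:::log_kernel(2)
  expect_lt(abs(sum(k)), 1e-12)

  # impulse at the center of a zero image: correlation returns the kernel.
  # The analytic oracle shares the 4*sigma truncation and re-centering.
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  resp <- log_filter(img, 2, rescale = FALSE)
  x <- -8:8  # 4 * sigma support
  r2 <- outer(x^2, x^2, "+")
  analytic <- (r2 - 2 * 4) / 16 * exp(-r2 / 8)
  analytic <- analytic - mean(analytic)
  expect_equal(resp[9:25, 9:25], analytic, tolerance = 1e-6)
  # no response outside the truncated support
  expect_equal(resp[1:8, ], matrix(0, 8, 33))

  # flat image: identically zero response before rescale
  expect_equal(log_filter(matrix(55, 9, 9), 1.5, rescale = FALSE),
               matrix(0, 9, 9), tolerance = 1e-10)
  # rescaled output of a flat image follows the degenerate-range rule
  expect_equal(log_filter(matrix(55, 9, 9), 1.5), matrix(0, 9, 9))
})

test_that("structure tensor orientation and positive semidefiniteness", {
  f0 <- structure_tensor(matrix(3, 16, 16))
  expect_equal(f0$J11, matrix(0, 16, 16), tolerance = 1e-12)
  expect_equal(f0$angle, matrix(0, 16, 16))

  # vertical step edge: gradient horizontal, dominant angle ~ 0
  step <- cbind(matrix(0, 24, 12), matrix(200, 24, 12))
  fs <- structure_tensor(step, 1, 2)
  mid <- fs$angle[12, 11:14]
  expect_lt(max(abs(mid)), 1e-3)

  set.seed(9)
  for (i in 1:10) {
    f <- structure_tensor(rand_img(12, 12), 1, 1.5)
    tr <- f$J11 + f$J22
    det2 <- f$J11 * f$J22 - f$J12^2
    mineig <- (tr - sqrt(pmax(tr^2 - 4 * det2, 0))) / 2
    expect_gte(min(mineig), -1e-9)
    expect_true(all(f$angle >= -pi / 2 & f$angle < pi / 2))
  }
})

test_that("diffusion tensor maps coherence to the stated eigenvalues", {
  z <- structure_tensor(matrix(1, 8, 8))
  D <- diffusion_tensor(z, alpha = 0.1, coherence_scale = 100)
  expect_equal(D$D11, matrix(0.1, 8, 8))
  expect_equal(D$D22, matrix(0.1, 8, 8))
  expect_equal(D$D12, matrix(0, 8, 8))

  # strongly oriented tensor: along-structure diffusivity approaches 1
  f <- list(J11 = matrix(1e9, 1, 1), J12 = matrix(0, 1, 1),
            J22 = matrix(0, 1, 1), angle = matrix(0, 1, 1))
  class(f) <- "orientation_field"
  D <- diffusion_tensor(f, alpha = 0.05, coherence_scale = 1)
  expect_equal(D$D22[1, 1], 1, tolerance = 1e-6)  # along the vertical structure
  expect_equal(D$D11[1, 1], 0.05)                 # across it

  # random PSD tensors: eigenvalues within [alpha, 1], eigenvectors preserved
  set.seed(3)
  for (i in 1:20) {
    g <- c(rnorm(1), rnorm(1))
    J <- outer(g, g) * runif(1, 0.1, 100)
    th <- 0.5 * atan2(2 * J[1, 2], J[1, 1] - J[2, 2])
    f <- list(J11 = matrix(J[1, 1], 1, 1), J12 = matrix(J[1, 2], 1, 1),
              J22 = matrix(J[2, 2], 1, 1), angle = matrix(th, 1, 1))
    class(f) <- "orientation_field"
    D <- diffusion_tensor(f, alpha = 0.05, coherence_scale = 10)
    Dm <- matrix(c(D$D11, D$D12, D$D12, D$D22), 2, 2)
    ev <- eigen(Dm, symmetric = TRUE)
    expect_gte(min(ev$values), 0.05 - 1e-9)
    expect_lte(max(ev$values), 1 + 1e-9)
    # principal axes of D align with the structure tensor's
    vJ <- eigen(J, symmetric = TRUE)$vectors[, 1]
    vD <- ev$vectors[, which.min(ev$values)]  # min diffusivity across structure
    expect_equal(abs(sum(vJ * vD)), 1, tolerance = 1e-9)
  }
})

test_that("diffusion respects fixed points, conservation and min-max", {
  # constant image: one iteration, unchanged
  d <- diffuse(matrix(7, 16, 16))
  expect_identical(d$image, matrix(7, 16, 16))
  expect_equal(d$iterations, 1L)

  # interior-supported image: mean conserved per iteration
  m <- matrix(0, 32, 32); m[10:22, 10:22] <- 100
  d2 <- diffuse(m, diffusion_config(max_iters = 5, entropy_tol = 0))
  expect_lt(abs(mean(d2$image) - mean(m)), 1e-6 * 255)

  # min-max principle at the largest admissible step
  set.seed(14)
  for (i in 1:5) {
    img <- rand_img(24, 24)
    out <- diffuse(img, diffusion_config(dt = 0.25, max_iters = 10,
                                         entropy_tol = 0))$image
    expect_lte(max(out), max(img) + 1e-6)
    expect_gte(min(out), min(img) - 1e-6)
  }
})

test_that("identity diffusion tensor reproduces the explicit heat equation", {
  set.seed(25)
  img <- rand_img(16, 16)
  Did <- list(D11 = matrix(1, 16, 16), D12 = matrix(0, 16, 16),
              D22 = matrix(1, 16, 16))
  rhs <- mammoenhance:::diffusion_step_rhs(img, Did)
  expect_equal(rhs, o_laplace5(img), tolerance = 1e-9)
})

test_that("entropy stopping terminates and the trace is finite", {
  set.seed(2)
  img <- rand_img(32, 32)
  d <- diffuse(img, diffusion_config(max_iters = 8, entropy_tol = 1e9))
  expect_equal(d$iterations, 1L)  # absurd tolerance stops immediately
  d2 <- diffuse(img, diffusion_config(max_iters = 8, entropy_tol = 0))
  expect_equal(d2$iterations, 8L)
  expect_true(all(is.finite(d2$entropy_trace)))
  expect_length(d2$entropy_trace, 9L)
})

test_that("oriented diffusion preserves stripe contrast better than blur", {
  # noisy horizontal stripes: coherent structure along rows
  set.seed(6)
  n <- 64L; f <- 4L  # 4 cycles over 64 rows
  stripes <- matrix(rep(128 + 60 * sin(2 * pi * f * (0:(n - 1)) / n), n), n)
  noisy <- pmin(pmax(stripes + matrix(rnorm(n * n, 0, 10), n), 0), 255)

  amp_at_f <- function(img) {
    pr <- rowMeans(img)
    Mod(fft(pr - mean(pr)))[f + 1L] / n
  }
  resid_noise <- function(img) {
    # variance along stripes (within rows), structure removed by row-centering
    mean(apply(img, 1, var))
  }

  dif <- diffuse(noisy, diffusion_config(alpha = 0.01, coherence_scale = 1e4,
                                         max_iters = 30, entropy_tol = 0))$image
  # isotropic blur matched to at least the diffusion's noise reduction
  sig <- 0.5
  repeat {
    blur <- mammoenhance:::gauss_smooth(noisy, sig)
    if (resid_noise(blur) <= resid_noise(dif) || sig > 8) break
    sig <- sig + 0.25
  }
  a0 <- amp_at_f(noisy)
  expect_gte(amp_at_f(dif), 0.9 * a0)      # stripe contrast preserved
  expect_lt(amp_at_f(blur), amp_at_f(dif)) # blur attenuates it more
  expect_lt(resid_noise(dif), resid_noise(noisy))  # and noise went down
})
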