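# Independent brute-force oracles.  Everything here is written as plain
# loops / closed forms so it shares no code path with the implementation.

rand_img <- function(h, w, lo = 0, hi = 255) {
  matrix(runif(h * w, lo, hi), h, w)
}

# --- morphology: sliding-window min/max with replicate border ---------------

o_window_stat <- function(img, fp, stat) {
  h <- nrow(img); w <- ncol(img)
  ar <- nrow(fp) %/% 2; ac <- ncol(fp) %/% 2
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      vals <- c()
      for (i in seq_len(nrow(fp))) {
        for (j in seq_len(ncol(fp))) {
          if (!fp[i, j]) next
          rr <- min(max(r + i - ar - 1L, 1L), h)
          cc <- min(max(c + j - ac - 1L, 1L), w)
          vals <- c(vals, img[rr, cc])
        }
      }
      out[r, c] <- stat(vals)
    }
  }
  out
}

o_erode <- function(img, fp) o_window_stat(img, fp, min)
o_dilate <- function(img, fp) o_window_stat(img, fp, max)
o_open <- function(img, fp) o_dilate(o_erode(img, fp), fp)
o_close <- function(img, fp) o_erode(o_dilate(img, fp), fp)
o_top_hat <- function(img, fp) img - o_open(img, fp)
o_bottom_hat <- function(img, fp) o_close(img, fp) - img

# --- metrics: elementwise loop oracles --------------------------------------

o_mse <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  s / length(x)
}

o_psnr <- function(x, y, variant) {
  m <- o_mse(x, y)
  if (variant == "as_printed") 10 * log10((255 - 1) / m)
  else 10 * log10(255^2 / m)
}

o_contrast_db <- function(y) {
  s1 <- 0; s2 <- 0
  for (i in seq_along(y)) {
    s1 <- s1 + y[i]
    s2 <- s2 + y[i]^2
  }
  n <- length(y)
  10 * log10(s2 / n - (s1 / n)^2)
}

o_eme <- function(y, k1, k2, eps = 1) {
  h <- nrow(y); w <- ncol(y)
  bw <- w %/% k1; bh <- h %/% k2
  tot <- 0
  for (l in seq_len(k2)) {
    for (k in seq_len(k1)) {
      r1 <- (l - 1L) * bh + 1L
      r2 <- if (l == k2) h else l * bh
      c1 <- (k - 1L) * bw + 1L
      c2 <- if (k == k1) w else k * bw
      mx <- -Inf; mn <- Inf
      for (r in r1:r2) for (c in c1:c2) {
        mx <- max(mx, y[r, c]); mn <- min(mn, y[r, c])
      }
      tot <- tot + 20 * log10(max(mx, eps) / max(mn, eps))
    }
  }
  tot / (k1 * k2)
}

# --- symmetric 3x3 eigensolver via the characteristic polynomial ------------

o_eigen3_sym <- function(A) {
  p1 <- A[1, 2]^2 + A[1, 3]^2 + A[2, 3]^2
  if (p1 < 1e-300) {
    ev <- sort(diag(A), decreasing = TRUE)
    V <- diag(3)[, order(diag(A), decreasing = TRUE)]
    return(list(values = ev, vectors = V))
  }
  q <- sum(diag(A)) / 3
  p2 <- sum((diag(A) - q)^2) + 2 * p1
  p <- sqrt(p2 / 6)
  B <- (A - q * diag(3)) / p
  r <- det(B) / 2
  r <- min(max(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  vals <- c(e1, e2, e3)
  vecs <- sapply(vals, function(lam) {
    M <- A - lam * diag(3)
    cr <- rbind(pracma_cross(M[1, ], M[2, ]),
                pracma_cross(M[1, ], M[3, ]),
                pracma_cross(M[2, ], M[3, ]))
    nrm <- sqrt(rowSums(cr^2))
    v <- cr[which.max(nrm), ]
    v / sqrt(sum(v^2))
  })
  list(values = vals, vectors = vecs)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# independent PCA gray: explicit loops + closed-form eigensolver
o_pca_gray <- function(img) {
  ycc <- to_ycbcr(img)   # the color transform itself is the shared contract
  X <- rbind(as.vector(ycc$Y), as.vector(ycc$Cb), as.vector(ycc$Cr))
  n <- ncol(X)
  for (i in 1:3) X[i, ] <- X[i, ] - mean(X[i, ])
  C <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) C[i, j] <- sum(X[i, ] * X[j, ]) / n
  e <- o_eigen3_sym(C)
  g <- numeric(n)
  lam <- pmax(e$values, 0)
  w <- lam / sum(lam)
  for (i in 1:3) {
    v <- e$vectors[, i]
    a <- abs(v)
    im <- which(a == max(a))[1]
    if (v[im] < 0) v <- -v
    g <- g + w[i] * as.vector(v %*% X)
  }
  lo <- min(g); hi <- max(g)
  array((g - lo) * 255 / (hi - lo), dim(img$red))
}

# --- 1-D k-means global optimum by dynamic programming ----------------------

o_kmeans_dp <- function(v, k) {
  x <- sort(v)
  n <- length(x)
  cs <- cumsum(x); css <- cumsum(x^2)
  cost <- function(j, i) {  # cost of one cluster covering x[j..i]
    s <- cs[i] - if (j > 1) cs[j - 1] else 0
    ss <- css[i] - if (j > 1) css[j - 1] else 0
    ss - s^2 / (i - j + 1)
  }
  D <- matrix(Inf, k, n)
  for (i in 1:n) D[1, i] <- cost(1, i)
  for (kk in 2:k) {
    for (i in kk:n) {
      js <- kk:i
      D[kk, i] <- min(D[kk - 1, js - 1] +
                        vapply(js, function(j) cost(j, i), numeric(1)))
    }
  }
  D[k, n]
}

# --- misc -------------------------------------------------------------------

o_confusion <- function(pred, truth) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1
    else if (pred[i] && !truth[i]) fp <- fp + 1
    else if (!pred[i] && truth[i]) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

o_dice <- function(a, b) {
  inter <- 0
  for (i in seq_along(a)) if (a[i] && b[i]) inter <- inter + 1
  2 * inter / (sum(a) + sum(b))
}

# inclusive point-in-triangle rasterization count by barycentric coordinates
o_triangle_count <- function(h, w, A, B, C) {
  den <- (B[1] - A[1]) * (C[2] - A[2]) - (C[1] - A[1]) * (B[2] - A[2])
  cnt <- 0
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      l1 <- ((r - A[1]) * (C[2] - A[2]) - (C[1] - A[1]) * (c - A[2])) / den
      l2 <- ((B[1] - A[1]) * (c - A[2]) - (r - A[1]) * (B[2] - A[2])) / den
      if (l1 >= -1e-9 && l2 >= -1e-9 && l1 + l2 <= 1 + 1e-9) cnt <- cnt + 1
    }
  }
  cnt
}

# 5-point Laplacian with replicate borders
o_laplace5 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  gv <- function(r, c) img[min(max(r, 1), h), min(max(c, 1), w)]
  for (r in seq_len(h)) for (c in seq_len(w))
    out[r, c] <- gv(r + 1, c) + gv(r - 1, c) + gv(r, c + 1) + gv(r, c - 1) -
      4 * img[r, c]
  out
}

# connectivity check by flood fill from the first true pixel
o_connected <- function(mask, connectivity = 8) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(TRUE)
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  stack <- list(idx[1, ])
  seen[idx[1, 1], idx[1, 2]] <- TRUE
  moves <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (m in seq_len(nrow(moves))) {
      r <- p[1] + moves[m, 1]; c <- p[2] + moves[m, 2]
      if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  sum(seen) == sum(mask)
}
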