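#' K-means clustering of image intensities
#'
#' Lloyd iterations on the 1-D intensity values with deterministic
#' initialization at k evenly spaced quantiles (probabilities
#' \eqn{(i - 1/2)/k}), which makes runs reproducible without a seed; a
#' random-initialization mode (\code{init = "random"}, k distinct values
#' sampled under \code{seed}) is kept for parity with common practice.
#' Convergence when the largest centroid movement is below \code{1e-6} or
#' after 300 iterations.  Centroids are reported sorted ascending with
#' labels remapped accordingly.
#'
#' @param img numeric matrix (or vector) of intensities.
#' @param k number of clusters, 2--8.
#' @param seed RNG seed (used by \code{init = "random"} only).
#' @param init \code{"quantile"} (default, deterministic) or \code{"random"}.
#' @return list of class \code{"cluster_result"}: \code{labels} (integer
#'   matrix in \code{0:(k-1)}, same shape as the input), \code{centroids}
#'   (sorted ascending), \code{k}, \code{withinss} (within-cluster sum of
#'   squares), \code{iterations}.
#' @export
kmeans_intensity <- function(img, k, seed = 1L,
                             init = c("quantile", "random")) {
  init <- match.arg(init)
  dm <- dim(img)
  v <- as.numeric(img)
  if (!all(is.finite(v))) stop("kmeans_intensity: non-finite intensities")
  k <- as.integer(k)
  if (k < 2L || k > 8L) stop("kmeans_intensity: k must be in [2, 8]")
  uv <- unique(v)
  if (length(uv) < k)
    stop("kmeans_intensity: fewer than k distinct intensity values")
  cen <- if (init == "quantile") {
    ci <- unname(quantile(v, probs = (seq_len(k) - 0.5) / k))
    # quantile init can collide on heavily tied data; fall back to distinct values
    if (anyDuplicated(ci)) sort(uv)[round(seq(1, length(uv), length.out = k))]
    else ci
  } else {
    with_seed(seed, sort(sample(uv, k)))
  }
  iters <- 0L
  for (it in seq_len(300L)) {
    d <- abs(outer(v, cen, "-"))
    lab <- max.col(-d, ties.method = "first")
    newc <- vapply(seq_len(k), function(i) {
      vi <- v[lab == i]
      if (length(vi)) mean(vi) else cen[i]
    }, numeric(1))
    iters <- it
    moved <- max(abs(newc - cen))
    cen <- newc
    if (moved < 1e-6) break
  }
  o <- order(cen)
  remap <- integer(k); remap[o] <- seq_len(k)
  lab <- remap[lab]
  cen <- cen[o]
  wss <- sum((v - cen[lab])^2)
  labels <- lab - 1L
  if (!is.null(dm)) dim(labels) <- dm
  structure(list(labels = labels, centroids = cen, k = k,
                 withinss = wss, iterations = iters),
            class = "cluster_result")
}

#' Binary mask from selected clusters
#'
#' Lesions are bright, so the default selection is the brightest cluster
#' (\code{k - 1} after the ascending-centroid remap).
#'
#' @param res a \code{cluster_result}.
#' @param which integer cluster ids in \code{0:(k-1)}.
#' @return logical matrix, true where the pixel's label is in \code{which}.
#' @export
mask_from_clusters <- function(res, which = res$k - 1L) {
  stopifnot(inherits(res, "cluster_result"))
  if (length(which) == 0) {
    warning("mask_from_clusters: empty selection; returning empty mask")
    return(array(FALSE, dim(res$labels)))
  }
  if (any(which < 0 | which >= res$k))
    stop("mask_from_clusters: cluster ids must be in [0, k)")
  array(res$labels %in% which, dim(res$labels))
}

#' Confusion-matrix evaluation of a predicted mask
#'
#' @param pred,truth logical matrices of identical shape.
#' @return named numeric vector \code{(specificity, sensitivity, accuracy)},
#'   each in \eqn{[0, 1]}; an undefined ratio (empty positive or negative
#'   class) is reported as \code{NA} with a warning.
#' @export
evaluate_mask <- function(pred, truth) {
  check_same_shape(pred, truth, "masks")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("evaluate_mask: no positive pixels in truth; sensitivity undefined")
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("evaluate_mask: no negative pixels in truth; specificity undefined")
    NA_real_
  }
  c(specificity = spec, sensitivity = sens,
    accuracy = (tp + tn) / (tp + fp + tn + fn))
}
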