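test_that("kmeans_intensity solves separable cases exactly", {
  img <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
  res <- kmeans_intensity(img, 2)
  expect_equal(res$centroids, c(10, 200))
  expect_equal(res$labels, array(as.integer(img > 105), dim(img)))

  # k equal to the number of distinct values: centroids are those values
  img3 <- matrix(rep(c(5, 90, 250), c(4, 8, 4)), 4, 4)
  res3 <- kmeans_intensity(img3, 3)
  expect_equal(res3$centroids, c(5, 90, 250))

  expect_error(kmeans_intensity(img, 1), "k must be")
  expect_error(kmeans_intensity(img, 9), "k must be")
  expect_error(kmeans_intensity(matrix(7, 3, 3), 2), "distinct")
})

test_that("kmeans_intensity reaches the 1-D dynamic-programming optimum", {
  set.seed(55)
  for (k in c(2L, 3L, 4L)) {
    means <- seq(55, 200, length.out = k)
    v <- unlist(lapply(means, function(m) rnorm(300, m, 10)))
    v <- pmin(pmax(v, 0), 255)
    res <- kmeans_intensity(matrix(v, nrow = 1), k)
    opt <- o_kmeans_dp(v, k)
    expect_lte(res$withinss, opt * 1.01)
    expect_gte(res$withinss, opt - 1e-6)  # cannot beat the global optimum
  }
  # two-Gaussian mixture: centroids near the DP-optimal ones
  v <- pmin(pmax(c(rnorm(500, 60, 10), rnorm(500, 180, 10)), 0), 255)
  res <- kmeans_intensity(matrix(v, 1), 2)
  expect_lt(abs(res$centroids[1] - 60), 3)
  expect_lt(abs(res$centroids[2] - 180), 3)
})

test_that("centroid order and label remap are consistent", {
  set.seed(70)
  v <- matrix(runif(300, 0, 255), 15, 20)
  res <- kmeans_intensity(v, 4)
  expect_equal(res$centroids, sort(res$centroids))
  for (i in 0:3) {
    px <- v[res$labels == i]
    d <- abs(outer(px, res$centroids, "-"))
    expect_true(all(max.col(-d, ties.method = "first") == i + 1))
  }
})

test_that("mask_from_clusters selects labels", {
  img <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
  res <- kmeans_intensity(img, 2)
  expect_equal(mask_from_clusters(res, 0:1), array(TRUE, c(4, 4)))
  expect_warning(m0 <- mask_from_clusters(res, integer(0)), "empty")
  expect_equal(m0, array(FALSE, c(4, 4)))
  expect_equal(mask_from_clusters(res), img > 105)
  expect_error(mask_from_clusters(res, 5), "ids")
})

test_that("lesion patch: brightest of k = 2 clusters overlaps the lesion", {
  ph <- lesion_patch(1L)
  deg <- to_ycbcr(ph$degraded)$Y
  res <- kmeans_intensity(deg, 2)
  expect_gte(dice(mask_from_clusters(res), ph$lesion_mask), 0.8)
})

test_that("evaluate_mask matches brute-force confusion counting", {
  truth <- matrix(FALSE, 10, 10); truth[2:4, 2:5] <- TRUE
  expect_equal(evaluate_mask(truth, truth),
               c(specificity = 1, sensitivity = 1, accuracy = 1))
  expect_equal(evaluate_mask(!truth, truth),
               c(specificity = 0, sensitivity = 0, accuracy = 0))

  # 100-pixel toy with tp=8, fn=2, tn=85, fp=5
  truth2 <- matrix(c(rep(TRUE, 10), rep(FALSE, 90)), 10, 10)
  pred2 <- matrix(c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 5),
                    rep(FALSE, 85)), 10, 10)
  cc <- o_confusion(pred2, truth2)
  expect_equal(unname(cc), c(8, 5, 85, 2))
  ev <- evaluate_mask(pred2, truth2)
  expect_equal(unname(ev["sensitivity"]), 0.8)
  expect_equal(unname(ev["specificity"]), 85 / 90)
  expect_equal(unname(ev["accuracy"]), 0.93)

  set.seed(12)
  for (i in 1:5) {
    p <- matrix(runif(64) > 0.5, 8, 8)
    t <- matrix(runif(64) > 0.5, 8, 8)
    cc <- o_confusion(p, t)
    ev <- evaluate_mask(p, t)
    expect_equal(unname(ev["sensitivity"]), cc["tp"] / (cc["tp"] + cc["fn"]),
                 ignore_attr = TRUE)
    expect_equal(unname(ev["specificity"]), cc["tn"] / (cc["tn"] + cc["fp"]),
                 ignore_attr = TRUE)
    # complement symmetry: sensitivity and specificity swap
    ev2 <- evaluate_mask(!p, !t)
    expect_equal(unname(ev2["sensitivity"]), unname(ev["specificity"]))
    expect_equal(unname(ev2["specificity"]), unname(ev["sensitivity"]))
  }
})

test_that("degenerate truths warn and return NA", {
  allpos <- matrix(TRUE, 4, 4)
  expect_warning(ev <- evaluate_mask(allpos, allpos), "specificity")
  expect_true(is.na(ev["specificity"]))
  expect_warning(ev2 <- evaluate_mask(!allpos, !allpos), "sensitivity")
  expect_true(is.na(ev2["sensitivity"]))
  expect_error(evaluate_mask(allpos, matrix(TRUE, 2, 2)), "dimensions")
})
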