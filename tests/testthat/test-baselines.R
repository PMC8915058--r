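test_that("hist_equalize follows the 256-bin CDF remap", {
  two <- matrix(c(rep(50, 8), rep(200, 8)), 4, 4)
  out <- hist_equalize(two)
  expect_setequal(unique(as.vector(out)), c(127, 255))  # floor(255 * CDF)
  expect_equal(out[two == 50][1], 127)
  expect_equal(out[two == 200][1], 255)

  # max is 255 for any non-constant input
  set.seed(19)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    o <- hist_equalize(img)
    expect_equal(max(o), 255)
    # intensity-monotone
    ord <- order(as.vector(img))
    expect_true(all(diff(as.vector(o)[ord]) >= 0))
  }

  # image with an exactly uniform histogram is (nearly) a fixed point
  u <- matrix(0:255, 16, 16)
  expect_lte(max(abs(hist_equalize(u) - u)), 1)
})

test_that("clahe degenerates to global equalization and stays flat on flats", {
  set.seed(23)
  img <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
  expect_lte(max(abs(clahe(img, Inf, c(1, 1)) - hist_equalize(img))), 1)
  flat <- clahe(matrix(77, 8, 8), 2, c(2, 2))
  expect_equal(max(flat) - min(flat), 0)  # constant in, constant out
  expect_error(clahe(img, 2, c(20, 2)), "tiles")

  # monotone for a global mapping
  o <- clahe(img, 4, c(1, 1))
  ord <- order(as.vector(img))
  expect_true(all(diff(as.vector(o)[ord]) >= -1e-9))
})

test_that("clahe equalizes tiles independently (per-tile oracle at centers)", {
  img <- matrix(0, 32, 32)
  pairs <- list(c(20, 80), c(40, 160), c(10, 210), c(100, 230))
  q <- 0
  for (br in 0:1) for (bc in 0:1) {
    q <- q + 1
    tile <- matrix(rep(pairs[[q]], each = 8), 16, 16)
    img[br * 16 + 1:16, bc * 16 + 1:16] <- tile
  }
  out <- clahe(img, Inf, c(2, 2))
  # outside the span of the tile centers the mapping is the pure per-tile
  # equalization; the image's outer corners are the cleanest probes
  q <- 0
  for (br in 0:1) for (bc in 0:1) {
    q <- q + 1
    tile_vals <- img[br * 16 + 1:16, bc * 16 + 1:16]
    he <- hist_equalize(tile_vals)
    r0 <- if (br == 0) 1L else 32L
    c0 <- if (bc == 0) 1L else 32L
    rt <- if (br == 0) 1L else 16L
    ct <- if (bc == 0) 1L else 16L
    expect_lte(abs(out[r0, c0] - he[rt, ct]), 1)
  }
})

test_that("clipping bounds the histogram slope", {
  # heavy spike plus sparse tail: clipping must flatten the spike's gain
  set.seed(29)
  img <- matrix(c(rep(100, 240), sample(0:255, 16)), 16, 16)
  unclipped <- clahe(img, Inf, c(1, 1))
  clipped <- clahe(img, 2, c(1, 1))
  # the spike maps lower once its histogram mass is clipped
  expect_lt(max(clipped[img == 100]), max(unclipped[img == 100]))
})

test_that("bbhe splits at the mean and equalizes each side", {
  # already-bimodal image is untouched
  bi <- matrix(c(rep(0, 8), rep(255, 8)), 4, 4)
  expect_equal(bbhe(bi), bi)

  # symmetric image: mean preserved within 2 intensity units
  sym <- matrix(rep(c(56, 120, 136, 200), each = 4), 4, 4)
  expect_lt(abs(mean(bbhe(sym)) - mean(sym)), 2)
  set.seed(41)
  symc <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  symc <- (symc + (255 - symc[16:1, 16:1])) / 2  # symmetrize about 127.5
  expect_lt(abs(mean(bbhe(symc)) - mean(symc)), 2)

  # three-value toy against the hand-computed two-sided CDF remap
  toy <- matrix(rep(c(10, 100, 240), c(4, 8, 4)), 4, 4)
  out <- bbhe(toy)
  expect_equal(out[toy == 10][1], 0)     # lower sub: min level anchors at 0
  expect_equal(out[toy == 100][1], 112)  # floor(112 * (1 - 1/3) / (2/3))
  expect_equal(out[toy == 240][1], 240)  # upper sub: single level, identity

  # monotone
  set.seed(43)
  img <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  o <- bbhe(img)
  ord <- order(as.vector(img))
  expect_true(all(diff(as.vector(o)[ord]) >= 0))

  expect_warning(cst <- bbhe(matrix(9, 3, 3)), "constant")
  expect_equal(cst, matrix(9, 3, 3))
})
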