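test_that("no-degradation spec reproduces the clean image in all channels", {
  sp <- phantom_spec(view = "MLO", height = 64, width = 64, lesions = NULL,
                     illumination_slope = 0, noise_sigma = 0)
  ph <- make_phantom(sp)
  expect_identical(ph$degraded$red, ph$clean)
  expect_identical(ph$degraded$green, ph$clean)
  expect_identical(ph$degraded$blue, ph$clean)
})

test_that("phantoms are bit-reproducible under a fixed seed", {
  sp <- phantom_spec(seed = 99L, height = 64, width = 64,
                     lesions = list(c(32, 20, 5, 60)))
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$clean, b$clean)
  expect_identical(a$degraded, b$degraded)
  expect_identical(a$lesion_mask, b$lesion_mask)
})

test_that("MLO pectoral triangle matches a brute-force point-in-triangle scan", {
  for (side in c("left", "right")) {
    sp <- phantom_spec(view = "MLO", side = side, height = 48, width = 40,
                       lesions = NULL, noise_sigma = 0)
    ph <- make_phantom(sp)
    h <- 48; w <- 40
    tri_h <- 0.45 * h; tri_w <- 0.38 * w
    # triangle vertices in (row, col): corner, down the chest wall, along the top
    if (side == "left") {
      A <- c(1, 1); B <- c(1 + tri_h, 1); C <- c(1, 1 + tri_w)
    } else {
      A <- c(1, w); B <- c(1 + tri_h, w); C <- c(1, w - tri_w)
    }
    expect_gt(sum(ph$pectoral_mask), 0)
    expect_equal(sum(ph$pectoral_mask), o_triangle_count(h, w, A, B, C))
    if (side == "left") {
      expect_true(ph$pectoral_mask[1, 1])
      expect_false(ph$pectoral_mask[h, w])
    } else {
      expect_true(ph$pectoral_mask[1, w])
      expect_false(ph$pectoral_mask[h, 1])
    }
  }
})

test_that("CC phantoms have an empty pectoral mask; masks are consistent", {
  ph <- make_phantom(phantom_spec(view = "CC", height = 64, width = 64,
                                  lesions = list(c(32, 20, 5, 60))))
  expect_equal(sum(ph$pectoral_mask), 0)
  for (seed in 1:5) {
    b <- random_phantom(seed, 64, "MLO")
    expect_true(all(b$breast_mask[b$lesion_mask]))      # lesion inside breast
    expect_false(any(b$pectoral_mask & b$lesion_mask))  # disjoint from muscle
  }
})

test_that("lesions outside the breast are rejected", {
  expect_error(make_phantom(phantom_spec(view = "CC", height = 64, width = 64,
                                         lesions = list(c(5, 60, 5, 50)))),
               "outside the breast")
})

test_that("degrade adds the stated ramp and noise, and clips", {
  m <- matrix(50, 8, 8)
  expect_identical(degrade(m, 0, 0), m)

  z <- matrix(0, 3, 4)
  expect_equal(degrade(z, 1, 0), matrix(rep(0:3, each = 3), 3, 4))

  # Monte-Carlo: sample sd of (output - input) near sigma
  const <- matrix(128, 256, 256)
  d <- degrade(const, 0, 5, seed = 11L)
  expect_gt(sd(d - const), 4.5)
  expect_lt(sd(d - const), 5.5)

  # clipping keeps the 8-bit range
  hi <- degrade(matrix(250, 16, 16), 2, 20, seed = 2L)
  expect_lte(max(hi), 255)
  expect_gte(min(hi), 0)
})

test_that("write_phantom emits images, masks and a parseable sidecar", {
  dir <- tempfile()
  ph <- make_phantom(phantom_spec(height = 48, width = 48, seed = 3L,
                                  lesions = list(c(26, 16, 4, 60))))
  write_phantom(ph, dir)
  files <- list.files(dir)
  expect_true(all(c("clean.png", "degraded_green.png", "breast_mask.png",
                    "pectoral_mask.png", "lesion_mask.png", "spec.txt")
                  %in% files))
  kv <- read.table(file.path(dir, "spec.txt"), sep = "=", as.is = TRUE)
  expect_equal(kv$V2[kv$V1 == "seed"], "3")
  # masks decode to exactly {0, 255}
  mk <- read_image(file.path(dir, "lesion_mask.png"))$red
  expect_setequal(unique(as.vector(mk)), c(0, 255))
  expect_equal(mk > 127, ph$lesion_mask)
})
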