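# Shared fixtures, built in code at test time.

# breast-tissue ROI patch: uniform tissue with one clipped bright lesion,
# the fixture on which k = 2 clustering isolates the lesion
lesion_patch <- function(seed, size = 128L) {
  make_phantom(phantom_spec(
    view = "CC", height = size, width = size,
    breast_intensity = 120, background_intensity = 120,
    lesions = list(c(round(size / 2), round(size * 0.375),
                     max(6, round(size * 0.09)), 150)),
    illumination_slope = 0.08, noise_sigma = 8, seed = seed))
}

# small noiseless MLO phantom with the intensity triple 200/120/20
clean_mlo <- function(size = 96L, side = "left") {
  make_phantom(phantom_spec(
    view = "MLO", side = side, height = size, width = size,
    breast_intensity = 120, background_intensity = 20,
    pectoral_intensity = 200, lesions = NULL,
    illumination_slope = 0, noise_sigma = 0, seed = 1L))
}

tmp_png <- function(img) {
  f <- tempfile(fileext = ".png")
  write_image(img, f)
  f
}
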