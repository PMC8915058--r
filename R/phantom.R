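#' Specify a synthetic mammogram phantom
#'
#' The phantom emulates the geometry the two standard screening projections
#' show: a breast rendered as a half-ellipse anchored to the chest-wall edge
#' of the frame, and (in the MLO projection only) the pectoral muscle as a
#' bright filled right triangle in the top chest-wall corner.  Lesions are
#' bright clipped 2-D Gaussian bumps added inside the breast.  A degraded
#' three-channel version adds a linear illumination ramp and zero-mean
#' Gaussian noise, drawn independently per channel with the red and blue
#' channels 1.25x noisier than the green, mimicking the channel asymmetry of
#' consumer-format mammograms.
#'
#' The ground-truth lesion mask is the 1/e-amplitude disk of each bump:
#' \code{radius} is the radius at which the bump has fallen to \eqn{1/e} of
#' its peak (the Gaussian-beam-waist convention), so the Gaussian sigma is
#' \code{radius / sqrt(2)}.
#'
#' @param view \code{"CC"} (craniocaudal, no pectoral muscle) or \code{"MLO"}
#'   (mediolateral oblique, pectoral triangle present).
#' @param side chest-wall side of the frame, \code{"left"} or \code{"right"}.
#' @param height,width raster size in pixels.
#' @param breast_intensity,background_intensity,pectoral_intensity mean
#'   intensities (0--255 scale) of the three regions.
#' @param lesions list of lesions, each \code{c(row, col, radius, amplitude)};
#'   \code{NULL} for none.
#' @param illumination_slope added ramp, intensity units per column.
#' @param noise_sigma Gaussian noise standard deviation (green channel).
#' @param seed integer RNG seed making the bundle bit-reproducible.
#' @return an object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(view = c("MLO", "CC"), side = c("left", "right"),
                         height = 256L, width = 256L,
                         breast_intensity = 120, background_intensity = 20,
                         pectoral_intensity = 200,
                         lesions = list(c(128, 80, 12, 80)),
                         illumination_slope = 0.08, noise_sigma = 8,
                         seed = 1L) {
  view <- match.arg(view); side <- match.arg(side)
  stopifnot(height >= 8, width >= 8, noise_sigma >= 0)
  for (v in c(breast_intensity, background_intensity, pectoral_intensity))
    if (v < 0 || v > 255) stop("phantom_spec: intensities must be in [0,255]")
  if (!is.null(lesions)) {
    for (l in lesions) {
      if (length(l) != 4) stop("phantom_spec: each lesion is (row,col,radius,amplitude)")
      if (l[3] < 1) stop("phantom_spec: lesion radius must be >= 1")
    }
  }
  structure(list(view = view, side = side, height = as.integer(height),
                 width = as.integer(width),
                 breast_intensity = breast_intensity,
                 background_intensity = background_intensity,
                 pectoral_intensity = pectoral_intensity,
                 lesions = lesions, illumination_slope = illumination_slope,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a phantom bundle
#'
#' @param spec a [phantom_spec].
#' @return list of class \code{"phantom_bundle"} with components
#'   \code{clean} (noise-free single-plane image), \code{degraded}
#'   ([rgb_image] with ramp + per-channel noise, clipped to \eqn{[0,255]}),
#'   and logical ground-truth masks \code{breast_mask}, \code{pectoral_mask},
#'   \code{lesion_mask}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  # chest-wall column coordinate: distance from the anchored edge
  xw <- if (spec$side == "left") cols - 1 else w - cols

  # breast: half-ellipse anchored to the chest wall edge
  ry <- 0.42 * h; rx <- 0.78 * w; cy <- 0.52 * h
  breast <- (xw / rx)^2 + ((rows - cy) / ry)^2 <= 1

  # MLO pectoral muscle: filled right triangle at the top chest-wall corner,
  # legs along the top edge and the chest wall
  pectoral <- matrix(FALSE, h, w)
  if (spec$view == "MLO") {
    tri_h <- 0.45 * h; tri_w <- 0.38 * w
    pectoral <- (rows - 1) / tri_h + xw / tri_w <= 1
  }

  clean <- matrix(spec$background_intensity, h, w)
  clean[breast] <- spec$breast_intensity
  clean[pectoral] <- spec$pectoral_intensity

  lesion_mask <- matrix(FALSE, h, w)
  if (!is.null(spec$lesions)) {
    for (l in spec$lesions) {
      r0 <- l[1]; c0 <- l[2]; rad <- l[3]; amp <- l[4]
      d2 <- (rows - r0)^2 + (cols - c0)^2
      lmask <- d2 <= rad^2
      if (!all(breast[lmask]))
        stop("make_phantom: lesion at (", r0, ",", c0, ") falls outside the breast")
      if (any(pectoral[lmask]))
        stop("make_phantom: lesion at (", r0, ",", c0, ") overlaps the pectoral muscle")
      sig <- rad / sqrt(2)  # mask radius = 1/e amplitude contour
      clean <- clean + amp * exp(-d2 / (2 * sig^2)) * breast
      lesion_mask <- lesion_mask | lmask
    }
  }
  clean <- clip255(clean)

  sig_g <- spec$noise_sigma
  sig_rb <- 1.25 * sig_g
  ch <- with_seed(spec$seed, {
    lapply(c(r = sig_rb, g = sig_g, b = sig_rb), function(s) {
      degrade_plane(clean, spec$illumination_slope, s)
    })
  })

  structure(list(clean = clean,
                 degraded = rgb_image(ch$r, ch$g, ch$b),
                 breast_mask = breast, pectoral_mask = pectoral,
                 lesion_mask = lesion_mask, spec = spec),
            class = "phantom_bundle")
}

# ramp + noise + clip, using the current RNG stream
degrade_plane <- function(img, slope, sigma) {
  h <- nrow(img); w <- ncol(img)
  ramp <- matrix(slope * (seq_len(w) - 1), h, w, byrow = TRUE)
  noise <- if (sigma > 0) matrix(rnorm(h * w, 0, sigma), h, w) else 0
  clip255(img + ramp + noise)
}

#' Degrade a single image plane
#'
#' Adds a column-wise linear illumination ramp (\code{slope * (col - 1)}) and
#' zero-mean Gaussian noise, then clips to \eqn{[0, 255]}.  Used by the
#' phantom generator and available standalone for building test inputs.
#'
#' @param img numeric matrix.
#' @param slope intensity units per column.
#' @param sigma noise standard deviation (\eqn{\ge 0}).
#' @param seed integer RNG seed.
#' @return degraded numeric matrix, same shape.
#' @export
degrade <- function(img, slope, sigma, seed = 1L) {
  img <- as_image(img)
  if (sigma < 0) stop("degrade: sigma must be >= 0")
  with_seed(seed, degrade_plane(img, slope, sigma))
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("phantom_bundle: %s view, %s side, %dx%d, %d lesion(s)\n",
              x$spec$view, x$spec$side, x$spec$height, x$spec$width,
              length(x$spec$lesions)))
  invisible(x)
}

#' Write a phantom bundle to disk
#'
#' Emits \code{clean.png}, the three degraded channel planes, the three
#' ground-truth masks, and a plain-text \code{spec.txt} sidecar with
#' \code{key=value} lines recording the generating parameters.
#'
#' @param bundle a \code{phantom_bundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_phantom <- function(bundle, dir) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(bundle$clean, file.path(dir, "clean.png"))
  for (p in c("red", "green", "blue"))
    write_image(bundle$degraded[[p]], file.path(dir, paste0("degraded_", p, ".png")))
  for (m in c("breast_mask", "pectoral_mask", "lesion_mask"))
    write_mask(bundle[[m]], file.path(dir, paste0(m, ".png")))
  s <- bundle$spec
  lesioncsv <- if (is.null(s$lesions)) "" else
    paste(vapply(s$lesions, function(l) paste(l, collapse = ","), ""),
          collapse = ";")
  lines <- c(paste0("view=", s$view), paste0("side=", s$side),
             paste0("height=", s$height), paste0("width=", s$width),
             paste0("breast_intensity=", s$breast_intensity),
             paste0("background_intensity=", s$background_intensity),
             paste0("pectoral_intensity=", s$pectoral_intensity),
             paste0("lesions=", lesioncsv),
             paste0("illumination_slope=", s$illumination_slope),
             paste0("noise_sigma=", s$noise_sigma), paste0("seed=", s$seed))
  writeLines(lines, file.path(dir, "spec.txt"))
  invisible(dir)
}
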