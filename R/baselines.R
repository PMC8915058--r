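# Comparator enhancers: global histogram equalization (HE), contrast-limited
# adaptive histogram equalization (CLAHE), and brightness-preserving
# bi-histogram equalization (BBHE).

# 256-bin histogram of an image rounded to integer levels
hist256 <- function(v) tabulate(pmin(pmax(round(v), 0), 255) + 1L, nbins = 256L)

#' Global histogram equalization
#'
#' Remaps intensity \eqn{v} to \eqn{\lfloor 255\, \mathrm{CDF}(v) \rfloor}
#' where the CDF is taken over 256 bins of the rounded input.  The output of
#' a non-constant image always reaches 255; the darkest level maps to
#' \eqn{\lfloor 255\, p_{min}\rfloor} where \eqn{p_{min}} is its own mass.
#'
#' @param img numeric matrix on the 0--255 scale.
#' @return equalized numeric matrix (integer levels).
#' @export
hist_equalize <- function(img) {
  img <- as_image(img)
  cdf <- cumsum(hist256(img)) / length(img)
  map <- floor(255 * cdf)
  array(map[pmin(pmax(round(img), 0), 255) + 1L], dim(img))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' The image is divided into a grid of tiles; each tile's 256-bin histogram
#' is clipped at \code{clip_limit} times the mean bin count (excess mass is
#' redistributed uniformly) and turned into an equalization mapping.  Each
#' pixel is remapped by bilinear interpolation between the mappings of the
#' four nearest tile centers (clamped at the image border).  With a single
#' tile and an infinite clip limit this degenerates to [hist_equalize].
#'
#' @param img numeric matrix on the 0--255 scale.
#' @param clip_limit histogram clip factor (> 0; \code{Inf} disables
#'   clipping).
#' @param tiles integer vector \code{c(rows, cols)} of the tile grid.
#' @return numeric matrix (fractional levels in \eqn{[0, 255]}).
#' @export
clahe <- function(img, clip_limit = 2, tiles = c(8L, 8L)) {
  img <- as_image(img)
  stopifnot(clip_limit > 0, length(tiles) == 2, all(tiles >= 1))
  tr <- as.integer(tiles[1]); tc <- as.integer(tiles[2])
  h <- nrow(img); w <- ncol(img)
  if (tr > h || tc > w) stop("clahe: more tiles than pixels along an axis")
  rb <- block_bounds(h, tr); cb <- block_bounds(w, tc)
  vq <- pmin(pmax(round(img), 0), 255)

  # per-tile equalization mappings (unfloored), 256 x tr x tc
  maps <- array(0, c(256L, tr, tc))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- vq[rb$from[i]:rb$to[i], cb$from[j]:cb$to[j]]
      hst <- tabulate(tile + 1L, nbins = 256L)
      if (is.finite(clip_limit)) {
        cl <- clip_limit * length(tile) / 256
        excess <- sum(pmax(hst - cl, 0))
        hst <- pmin(hst, cl) + excess / 256
      }
      maps[, i, j] <- 255 * cumsum(hst) / sum(hst)
    }
  }

  # bilinear interpolation between tile-center mappings
  rc <- (rb$from + rb$to) / 2
  cc <- (cb$from + cb$to) / 2
  ri <- findInterval(seq_len(h), rc, all.inside = TRUE)  # lower tile index
  ci <- findInterval(seq_len(w), cc, all.inside = TRUE)
  if (tr == 1L) { ri <- rep(1L, h); wr <- rep(0, h) } else {
    wr <- (seq_len(h) - rc[ri]) / (rc[ri + 1L] - rc[ri])
    wr <- pmin(pmax(wr, 0), 1)
  }
  if (tc == 1L) { ci <- rep(1L, w); wc <- rep(0, w) } else {
    wc <- (seq_len(w) - cc[ci]) / (cc[ci + 1L] - cc[ci])
    wc <- pmin(pmax(wc, 0), 1)
  }
  RI <- matrix(ri, h, w); WR <- matrix(wr, h, w)
  CI <- matrix(ci, h, w, byrow = TRUE); WC <- matrix(wc, h, w, byrow = TRUE)
  RI2 <- pmin(RI + 1L, tr); CI2 <- pmin(CI + 1L, tc)
  at <- function(R, C) {
    idx <- (vq + 1L) + (R - 1L) * 256L + (C - 1L) * (256L * tr)
    array(maps[idx], dim(img))
  }
  out <- (1 - WR) * (1 - WC) * at(RI, CI) + (1 - WR) * WC * at(RI, CI2) +
    WR * (1 - WC) * at(RI2, CI) + WR * WC * at(RI2, CI2)
  out
}

#' Brightness-preserving bi-histogram equalization (BBHE)
#'
#' Splits the histogram at the input mean \eqn{\mu} and equalizes the two
#' sub-histograms independently: levels \eqn{\le \mu} onto \eqn{[0, \mu]}
#' and levels \eqn{> \mu} onto \eqn{(\mu, 255]}.  Each sub-mapping is
#' anchored so its lowest occupied level keeps the range endpoint (a
#' sub-histogram with a single occupied level is left unchanged), which
#' preserves the mean of symmetric images and fixes already-bimodal ones.
#'
#' @param img numeric matrix on the 0--255 scale.
#' @return equalized numeric matrix; a constant image is returned unchanged
#'   with a warning.
#' @export
bbhe <- function(img) {
  img <- as_image(img)
  vq <- pmin(pmax(round(img), 0), 255)
  if (max(vq) == min(vq)) {
    warning("bbhe: constant image; returning unchanged")
    return(img)
  }
  mu <- mean(vq)
  lower <- vq <= mu
  out <- vq
  out[lower] <- sub_equalize(vq[lower], 0, floor(mu))
  out[!lower] <- sub_equalize(vq[!lower], ceiling(mu), 255)
  array(out, dim(img))
}

# anchored equalization of a set of levels onto [lo, hi]: the CDF is shifted
# so the lowest occupied level maps to lo and the top maps to hi
sub_equalize <- function(v, lo, hi) {
  hst <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(hst) / length(v)
  c0 <- cdf[which(hst > 0)[1]]
  if (c0 >= 1) return(v)  # single occupied level: identity
  map <- floor(lo + (hi - lo) * pmax(cdf - c0, 0) / (1 - c0))
  map[v + 1L]
}
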