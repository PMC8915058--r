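#' Read a raster image into three channel planes
#'
#' Digital mammograms are commonly stored as visually gray 3-channel JPEGs;
#' the pipeline always starts from the red, green and blue planes.  Grayscale
#' inputs are replicated into three identical planes so every later stage runs
#' unchanged.  Supported formats: PNG (8/16-bit), JPEG, PGM (plain \code{P2}
#' or binary \code{P5}, maxval up to 65535).  16-bit inputs are linearly
#' rescaled onto the 0--255 scale (\code{v * 255 / maxval}).  No colorspace
#' conversion is applied at read time: the planes are the file's own samples.
#'
#' TIFF is not supported in this build (no TIFF decoder is available);
#' convert to PNG first.
#'
#' @param path path to a PNG, JPEG or PGM file.
#' @return an [rgb_image] with planes on the 0--255 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  magic <- readBin(path, "raw", n = 4L)
  arr <- if (length(magic) >= 4 && identical(magic[2:4], charToRaw("PNG"))) {
    png::readPNG(path) * 255
  } else if (length(magic) >= 2 && magic[1] == as.raw(0xff) &&
             magic[2] == as.raw(0xd8)) {
    jpeg::readJPEG(path) * 255
  } else if (length(magic) >= 2 && magic[1] == charToRaw("P") &&
             rawToChar(magic[2]) %in% c("2", "5")) {
    read_pgm(path)
  } else if (ext %in% c("tif", "tiff")) {
    stop("read_image: TIFF is not supported in this build; convert to PNG: ",
         path)
  } else {
    stop("read_image: unreadable or unsupported raster: ", path)
  }
  if (is.matrix(arr)) return(rgb_image(arr, arr, arr))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 1L) {
      g <- arr[, , 1]
      return(rgb_image(g, g, g))
    }
    # channels 4+ (alpha) are dropped
    return(rgb_image(arr[, , 1], arr[, , 2], arr[, , 3]))
  }
  stop("read_image: zero-sized or malformed raster: ", path)
}

# internal PGM reader: P2 (ASCII) and P5 (binary), maxval <= 65535
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokenizer(con)
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("read_pgm: not a PGM file: ", path)
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop("read_pgm: zero-sized raster: ", path)
  if (is.na(maxv) || maxv < 1L) stop("read_pgm: invalid maxval: ", path)
  n <- w * h
  vals <- if (magic == "P5") {
    if (maxv > 255L) {
      as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                         endian = "big"))
    } else {
      as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE))
    }
  } else {
    txt <- readChar(con, nchars = 1e8, useBytes = TRUE)
    as.numeric(scan(text = txt, what = numeric(), comment.char = "#",
                    quiet = TRUE))
  }
  if (length(vals) < n) stop("read_pgm: truncated pixel data: ", path)
  # PGM is row-major (english reading order)
  matrix(vals[seq_len(n)], nrow = h, ncol = w, byrow = TRUE) * (255 / maxv)
}

# reads whitespace/comment-separated header tokens, leaving the connection
# positioned one byte past the token separator (required before P5 payload)
pgm_tokenizer <- function(con) {
  function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop("read_pgm: unexpected end of file")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
}

#' Write a single-plane image to disk
#'
#' Values must already be on the 0--255 scale; they are rounded half-to-even
#' to integers and written as an 8-bit single-channel raster.  PNG (lossless)
#' is the output format of record; \code{.pgm} writes binary P5.
#'
#' @param img numeric matrix with values in \eqn{[0, 255]}.
#' @param path destination ending in \code{.png} or \code{.pgm}.
#' @return invisibly, the path written.
#' @export
write_image <- function(img, path) {
  img <- as_image(img)
  if (min(img) < 0 || max(img) > 255)
    stop("write_image: values outside [0,255]; rescale first")
  q <- round(img)  # round() is round-half-to-even
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(q), nrow(q)), con, eos = NULL)
    writeBin(as.integer(t(q)), con, size = 1)
  } else {
    png::writePNG(q / 255, target = path)
  }
  invisible(path)
}

#' @describeIn write_image write a binary mask as an 8-bit PNG with values
#'   \{0, 255\}.
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  write_image(array(ifelse(mask, 255, 0), dim(mask)), path)
}
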