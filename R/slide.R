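#' Slide image container
#'
#' An in-memory single-resolution whole-slide raster together with its stain,
#' magnification and physical scale. The two supported magnifications follow
#' the acquisition protocol: 10x at 1 micron/pixel and 40x at 0.25
#' micron/pixel, so 40x rasters of the same tissue have exactly 4x the linear
#' dimensions of the 10x raster.
#'
#' @param pixels integer/numeric `H x W x 3` array with values in 0..255.
#' @param stain `"HE"` or `"PAS"`.
#' @param magnification `"10x"` or `"40x"`.
#' @param slide_id character scalar identifier.
#' @return object of class `slide_image` with fields `pixels`, `stain`,
#'   `magnification`, `mpp` (microns per pixel) and `slide_id`.
#' @export
slide_image <- function(pixels, stain, magnification, slide_id) {
  stain <- match.arg(stain, c("HE", "PAS"))
  magnification <- match.arg(magnification, c("10x", "40x"))
  dm <- dim(pixels)
  if (length(dm) != 3L || dm[3L] != 3L || dm[1L] < 1L || dm[2L] < 1L) {
    stop("pixels must be an H x W x 3 array with H, W >= 1")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in 0..255")
  }
  structure(
    list(
      pixels = pixels,
      stain = stain,
      magnification = magnification,
      mpp = mpp_for(magnification),
      slide_id = as.character(slide_id)
    ),
    class = "slide_image"
  )
}

#' Microns per pixel for a magnification
#' @param magnification `"10x"` or `"40x"`.
#' @return numeric scalar (1.0 at 10x, 0.25 at 40x).
#' @export
mpp_for <- function(magnification) {
  switch(match.arg(magnification, c("10x", "40x")), "10x" = 1.0, "40x" = 0.25)
}

#' @export
print.slide_image <- function(x, ...) {
  dm <- dim(x$pixels)
  cat(sprintf(
    "<slide_image %s: %s %s, %d x %d px, %.2f um/px>\n",
    x$slide_id, x$stain, x$magnification, dm[2L], dm[1L], x$mpp
  ))
  invisible(x)
}

#' Integer luminance image of a slide
#'
#' Rec. 601 luma (0.299 R + 0.587 G + 0.114 B), rounded to 0..255.
#'
#' @param slide `slide_image` or H x W x 3 array.
#' @return integer matrix.
#' @export
luminance <- function(slide) {
  px <- if (inherits(slide, "slide_image")) slide$pixels else slide
  lum <- 0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
  matrix(as.integer(round(lum)), nrow = dim(px)[1L])
}

#' Write / read binary PPM (netpbm P6) rasters
#'
#' Lossless 8-bit RGB container writable and readable with base R; used as the
#' on-disk raster format for the command line tools (no TIFF/PNG codec is
#' assumed to be installed).
#'
#' @param img `slide_image` or H x W x 3 array of 0..255 values.
#' @param path file path.
#' @return `read_ppm` returns an integer H x W x 3 array.
#' @export
write_ppm <- function(img, path) {
  px <- if (inherits(img, "slide_image")) img$pixels else img
  dm <- dim(px)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", dm[2L], dm[1L]), con, eos = NULL)
  # interleave RGB row-major
  arr <- aperm(px, c(3L, 2L, 1L))
  writeBin(as.raw(as.integer(arr)), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stop("unexpected end of PPM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
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
  magic <- read_token()
  if (magic != "P6") stop("not a binary PPM (P6) file: ", path)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (maxval != 255L) stop("only maxval 255 PPM supported")
  raw <- readBin(con, "raw", n = 3L * w * h)
  arr <- array(as.integer(raw), dim = c(3L, w, h))
  aperm(arr, c(3L, 2L, 1L))
}
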