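#' Sliding-window tiling configuration
#'
#' Window side `n` is 700 px at 10x and 2800 px at 40x; the stride is always
#' `0.5 * n`; extracted patches are padded to `n x n` and rescaled to the
#' model input side (`target_size`): 768 px for 10x patches, 1024 px for 40x
#' patches.
#'
#' @param n window side in pixels (even).
#' @param target_size model input side after pad + resize.
#' @param stride sliding stride; must equal `n / 2`.
#' @param pad_value background fill for short edge tiles (255 = white).
#' @return object of class `tile_config`.
#' @export
tile_config <- function(n, target_size, stride = n / 2, pad_value = 255) {
  n <- as.integer(n)
  if (n %% 2L != 0L) stop("window side n must be even")
  if (stride != n / 2) stop("stride must equal n / 2")
  if (target_size < 1) stop("target_size must be >= 1")
  structure(
    list(
      n = n, stride = as.integer(stride),
      target_size = as.integer(target_size), pad_value = pad_value
    ),
    class = "tile_config"
  )
}

#' @rdname tile_config
#' @param magnification `"10x"` or `"40x"`: returns the standard configuration
#'   (700 -> 768 at 10x, 2800 -> 1024 at 40x).
#' @export
tile_config_for <- function(magnification = c("10x", "40x")) {
  switch(match.arg(magnification),
    "10x" = tile_config(700L, 768L),
    "40x" = tile_config(2800L, 1024L)
  )
}

#' Otsu threshold of an integer-valued image
#'
#' Exhaustively maximises the between-class variance over all 256 cut points
#' of the 8-bit histogram; ties (e.g. perfectly bimodal histograms) are broken
#' by the midpoint of the maximising range.
#'
#' @param lum integer matrix/vector of values in 0..255.
#' @return threshold `t` (may be fractional for tied maximisers); pixels with
#'   value `< t` are foreground. A single-valued histogram yields `t` equal to
#'   that value, i.e. empty foreground.
#' @export
otsu_threshold <- function(lum) {
  counts <- tabulate(as.integer(lum) + 1L, nbins = 256L)
  total <- sum(counts)
  levels <- 0:255
  if (sum(counts > 0L) <= 1L) return(levels[which(counts > 0L)][1L])
  w0 <- cumsum(as.numeric(counts)) / total
  mu <- cumsum(as.numeric(counts) * levels) / total
  mu_t <- mu[256L]
  w1 <- 1 - w0
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * w1)
  sigma_b[!is.finite(sigma_b)] <- -Inf
  best <- which(sigma_b == max(sigma_b)) - 1L
  mean(range(best)) + 0.5
}

#' Otsu foreground mask of a slide
#'
#' Converts to luminance, thresholds by Otsu, and marks pixels strictly below
#' the threshold as tissue foreground (tissue is darker than the near-white
#' glass background).
#'
#' @param slide a [slide_image()].
#' @return logical matrix, `TRUE` = foreground.
#' @export
foreground_mask <- function(slide) {
  lum <- luminance(slide)
  t <- otsu_threshold(lum)
  lum < t
}

#' Plan sliding-window tile origins over the foreground
#'
#' Origins lie on the lattice `{0, stride, 2 stride, ...}`; the final origin
#' is clamped so the last window ends exactly at the slide edge. Windows that
#' contain no foreground pixel are dropped, so every foreground pixel is
#' covered by at least one kept tile. A slide smaller than `n` yields the
#' single origin (0, 0) (the short crop is padded at extraction).
#'
#' @param mask logical foreground matrix (rows index y).
#' @param config a [tile_config()].
#' @return data.frame with columns `x0`, `y0` (0-based origins).
#' @export
plan_tiles <- function(mask, config) {
  stopifnot(is.logical(mask), inherits(config, "tile_config"))
  H <- nrow(mask); W <- ncol(mask)
  axis_origins <- function(extent) {
    if (extent <= config$n) return(0L)
    last <- extent - config$n
    lat <- seq.int(0L, extent - 1L, by = config$stride)
    sort(unique(c(lat[lat <= last], last)))
  }
  xs <- axis_origins(W)
  ys <- axis_origins(H)
  grid <- expand.grid(x0 = xs, y0 = ys, KEEP.OUT.ATTRS = FALSE)
  # integral image for fast any-foreground window queries
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(mask, 2L, cumsum), 1L, cumsum) |> t()
  win_sum <- function(x0, y0) {
    x1 <- pmin(x0 + config$n, W); y1 <- pmin(y0 + config$n, H)
    S[y1 + 1L, x1 + 1L] - S[y0 + 1L, x1 + 1L] -
      S[y1 + 1L, x0 + 1L] + S[y0 + 1L, x0 + 1L]
  }
  keep <- mapply(win_sum, grid$x0, grid$y0) > 0
  grid[keep, , drop = FALSE]
}

#' Patch transform record
#'
#' Records the exact mapping from a tile crop to the resized model patch so it
#' can be inverted without loss: crop at `(x0, y0)`, pad (right/bottom) to
#' `n x n`, scale by `s = target_size / n`. Patch coordinates map back to
#' slide coordinates as `x_slide = x_patch / s - pad_left + x0`.
#'
#' @param x0,y0 tile origin in slide pixels.
#' @param n raw window side.
#' @param scale `target_size / n`.
#' @param pad_left,pad_top pad offsets (0 for the clamped-tile policy).
#' @return object of class `patch_transform`.
#' @export
patch_transform <- function(x0, y0, n, scale, pad_left = 0, pad_top = 0) {
  structure(
    list(
      x0 = x0, y0 = y0, n = n, scale = scale,
      pad_left = pad_left, pad_top = pad_top
    ),
    class = "patch_transform"
  )
}

#' Extract one model-ready patch from a slide
#'
#' Crops the `n x n` window at `origin` (short at slide edges), pads the short
#' sides with `pad_value` to `n x n`, and rescales to
#' `target_size x target_size` by bilinear interpolation. The inverse mapping
#' is recorded in the returned [patch_transform()].
#'
#' @param slide a [slide_image()].
#' @param origin `c(x0, y0)` from [plan_tiles()].
#' @param config a [tile_config()].
#' @return list with `patch` (integer target^2 x 3 array) and `transform`.
#' @export
extract_patch <- function(slide, origin, config) {
  stopifnot(inherits(slide, "slide_image"), inherits(config, "tile_config"))
  x0 <- as.integer(origin[1L]); y0 <- as.integer(origin[2L])
  dm <- dim(slide$pixels); H <- dm[1L]; W <- dm[2L]
  on_lattice <- function(o, extent) {
    o == max(0L, extent - config$n) || (o %% config$stride == 0L && o + config$n <= extent)
  }
  if (x0 < 0 || y0 < 0 || !on_lattice(x0, W) || !on_lattice(y0, H)) {
    stop("origin (", x0, ",", y0, ") is not on the tile lattice")
  }
  cw <- min(config$n, W - x0); ch <- min(config$n, H - y0)
  crop <- array(config$pad_value, dim = c(config$n, config$n, 3L))
  crop[seq_len(ch), seq_len(cw), ] <-
    slide$pixels[y0 + seq_len(ch), x0 + seq_len(cw), , drop = FALSE]
  patch <- round(resize_bilinear(crop, config$target_size, config$target_size))
  storage.mode(patch) <- "integer"
  patch[] <- pmin(255L, pmax(0L, patch))
  list(
    patch = patch,
    transform = patch_transform(
      x0 = x0, y0 = y0, n = config$n, scale = config$target_size / config$n
    )
  )
}

#' Map a patch-space instance back to slide coordinates
#'
#' Applies the exact inverse of the pad + resize mapping recorded in a
#' [patch_transform()] to the instance polygon (and recomputes the tight
#' bbox). Round trips are exact to well below 0.5 px.
#'
#' @param instance a [wsi_instance()] in patch space.
#' @param transform the [patch_transform()] of that patch.
#' @param slide_id optional slide id to stamp on the result.
#' @return the instance in slide space.
#' @export
to_slide_coords <- function(instance, transform, slide_id = instance$slide_id) {
  stopifnot(inherits(instance, "wsi_instance"), inherits(transform, "patch_transform"))
  poly <- instance$polygon
  poly[, 1L] <- poly[, 1L] / transform$scale - transform$pad_left + transform$x0
  poly[, 2L] <- poly[, 2L] / transform$scale - transform$pad_top + transform$y0
  wsi_instance(
    label = instance$label, polygon = poly, score = instance$score,
    slide_id = slide_id, magnification = instance$magnification
  )
}
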