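#' Polygon geometry primitives
#'
#' Polygons are n x 2 numeric matrices with columns `x`, `y` holding an open
#' ring (first vertex not repeated) in the shared 0-based pixel coordinate
#' frame: x rightward, y downward, pixel `(r, c)` covering the half-open cell
#' `[c, c+1) x [r, r+1)`.
#'
#' @param poly numeric matrix with two columns (x, y).
#' @return `poly_area` the unsigned enclosed area, `poly_perimeter` the ring
#'   length, `poly_centroid` the area centroid `c(x, y)`.
#' @name polygon-geometry
NULL

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2L || nrow(poly) < 3L) {
    stop("polygon must be a numeric matrix with >= 3 rows and columns (x, y)")
  }
  # drop an explicitly closed last vertex
  if (nrow(poly) > 3L && all(poly[1L, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  colnames(poly) <- c("x", "y")
  poly
}

poly_cross_terms <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  x * yn - xn * y
}

#' @rdname polygon-geometry
#' @export
poly_area <- function(poly) {
  poly <- as_polygon(poly)
  abs(sum(poly_cross_terms(poly))) / 2
}

#' @rdname polygon-geometry
#' @export
poly_perimeter <- function(poly) {
  poly <- as_polygon(poly)
  d <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

#' @rdname polygon-geometry
#' @export
poly_centroid <- function(poly) {
  poly <- as_polygon(poly)
  cr <- poly_cross_terms(poly)
  a <- sum(cr) / 2
  if (a == 0) return(colMeans(poly))
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' Second-moment ellipse of a polygon
#'
#' Area-normalised central second moments of the enclosed region, computed in
#' closed form by Green's theorem, and the axis lengths of the ellipse with
#' the same moments (for a solid ellipse with semi-axes a >= b the major axis
#' length is 2a, matching the usual region-properties convention
#' `4 * sqrt(lambda_max)`).
#'
#' @param poly polygon matrix.
#' @return list with `covariance` (2 x 2), `major_axis_length`,
#'   `minor_axis_length`, `orientation` (radians).
#' @export
poly_moments <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (a == 0) stop("degenerate polygon: zero area")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  sxx <- sum((x^2 + x * xn + xn^2) * cr) / (12 * a) - cx^2
  syy <- sum((y^2 + y * yn + yn^2) * cr) / (12 * a) - cy^2
  sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / (24 * a) -
    cx * cy
  cov <- matrix(c(sxx, sxy, sxy, syy), 2L, 2L)
  ev <- eigen(cov, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  list(
    covariance = cov,
    major_axis_length = 4 * sqrt(lam[1L]),
    minor_axis_length = 4 * sqrt(lam[2L]),
    orientation = atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L])
  )
}

#' Tight axis-aligned bounding box of a polygon
#'
#' @param poly polygon matrix.
#' @return numeric `c(x, y, w, h)` covering the half-open range
#'   `[x, x+w) x [y, y+h)`.
#' @export
poly_bbox <- function(poly) {
  poly <- as_polygon(poly)
  x0 <- min(poly[, 1L]); y0 <- min(poly[, 2L])
  c(x = x0, y = y0, w = max(poly[, 1L]) - x0, h = max(poly[, 2L]) - y0)
}

#' Even-odd point-in-polygon test
#'
#' Vectorised crossing-number test; points exactly on a vertical edge count
#' consistently via half-open edge spans.
#'
#' @param px,py point coordinates (equal length).
#' @param poly polygon matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  for (i in seq_len(n)) {
    if (y[i] == yn[i]) next
    crosses <- (y[i] <= py) != (yn[i] <= py)
    if (!any(crosses)) next
    xi <- x[i] + (py[crosses] - y[i]) * (xn[i] - x[i]) / (yn[i] - y[i])
    hit <- px[crosses] < xi
    idx <- which(crosses)[hit]
    inside[idx] <- !inside[idx]
  }
  inside
}

#' Rasterise a polygon by pixel-centre inclusion
#'
#' A pixel `(r, c)` is set iff its centre `(c + 0.5, r + 0.5)` lies inside the
#' polygon (even-odd rule), implemented as an exact scanline fill. Axis-aligned
#' integer rectangles rasterise to exactly `w * h` pixels.
#'
#' @param poly polygon matrix in raster coordinates.
#' @param width,height raster extent in pixels.
#' @return logical `height x width` matrix (rows index y).
#' @export
rasterize_polygon <- function(poly, width, height) {
  poly <- as_polygon(poly)
  mask <- matrix(FALSE, nrow = height, ncol = width)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  rows <- vector("list", nrow(poly))
  xs <- vector("list", nrow(poly))
  for (i in seq_len(nrow(poly))) {
    if (y[i] == yn[i]) next
    ylo <- min(y[i], yn[i]); yhi <- max(y[i], yn[i])
    r0 <- max(0L, as.integer(ceiling(ylo - 0.5)))
    r1 <- min(height - 1L, as.integer(ceiling(yhi - 0.5)) - 1L)
    if (r0 > r1) next
    r <- r0:r1
    yc <- r + 0.5
    keep <- yc >= ylo & yc < yhi
    r <- r[keep]; yc <- yc[keep]
    if (!length(r)) next
    rows[[i]] <- r
    xs[[i]] <- x[i] + (yc - y[i]) * (xn[i] - x[i]) / (yn[i] - y[i])
  }
  rows <- unlist(rows); crossings <- unlist(xs)
  if (!length(rows)) return(mask)
  o <- order(rows, crossings)
  rows <- rows[o]; crossings <- crossings[o]
  # pair consecutive crossings per row (even-odd)
  runs <- rle(rows)
  stopifnot(all(runs$lengths %% 2L == 0L))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg_r <- integer(0); seg_a <- numeric(0); seg_b <- numeric(0)
  for (k in seq_along(runs$values)) {
    idx <- seq(starts[k], ends[k])
    a <- crossings[idx[c(TRUE, FALSE)]]
    b <- crossings[idx[c(FALSE, TRUE)]]
    seg_r <- c(seg_r, rep.int(runs$values[k], length(a)))
    seg_a <- c(seg_a, a); seg_b <- c(seg_b, b)
  }
  c0 <- pmax(0L, as.integer(ceiling(seg_a - 0.5)))
  c1 <- pmin(width - 1L, as.integer(ceiling(seg_b - 0.5)) - 1L)
  keep <- c0 <= c1
  if (!any(keep)) return(mask)
  c0 <- c0[keep]; c1 <- c1[keep]; seg_r <- seg_r[keep]
  lens <- c1 - c0 + 1L
  cols <- sequence(lens) - 1L + rep.int(c0, lens)
  rws <- rep.int(seg_r, lens)
  mask[rws + 1L + as.numeric(cols) * height] <- TRUE
  mask
}

#' Vectorise a binary mask back to a polygon
#'
#' Traces the outer boundary of the mask's (single) connected component along
#' pixel cracks; the returned ring encloses exactly the component's pixels, so
#' its shoelace area equals the pixel count for simply connected masks.
#'
#' @param mask logical matrix (rows index y).
#' @return polygon matrix of lattice-corner vertices.
#' @export
mask_to_polygon <- function(mask) {
  stopifnot(is.logical(mask), any(mask))
  lab <- .cc_label_cpp(mask, 8L)
  ring <- .trace_outer_cpp(lab, 1L)
  as_polygon(ring)
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background) with attribute `n`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  .cc_label_cpp(mask, as.integer(connectivity))
}

#' Outer contour polygon of one labelled component
#'
#' @param labels integer label matrix from [label_components()].
#' @param id component id.
#' @return polygon matrix enclosing the component (holes included in area).
#' @export
component_polygon <- function(labels, id) {
  as_polygon(.trace_outer_cpp(labels, as.integer(id)))
}

#' Bilinear resize of a matrix or H x W x 3 array
#'
#' Pixel-centre aligned bilinear interpolation (half-pixel convention), the
#' deterministic rescale used by patch extraction. Constant inputs map to
#' constant outputs.
#'
#' @param img numeric matrix or 3-d array.
#' @param height,width output size.
#' @return resized matrix/array (numeric).
#' @export
resize_bilinear <- function(img, height, width) {
  dm <- dim(img)
  H <- dm[1L]; W <- dm[2L]
  src_r <- (seq_len(height) - 0.5) * H / height - 0.5
  src_c <- (seq_len(width) - 0.5) * W / width - 0.5
  src_r <- pmin(pmax(src_r, 0), H - 1)
  src_c <- pmin(pmax(src_c, 0), W - 1)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  r0 <- r0 + 1L; r1 <- r1 + 1L; c0 <- c0 + 1L; c1 <- c1 + 1L
  one_plane <- function(M) {
    outer(1 - fr, 1 - fc) * M[r0, c0, drop = FALSE] +
      outer(1 - fr, fc) * M[r0, c1, drop = FALSE] +
      outer(fr, 1 - fc) * M[r1, c0, drop = FALSE] +
      outer(fr, fc) * M[r1, c1, drop = FALSE]
  }
  if (length(dm) == 2L) return(one_plane(img))
  out <- array(0, dim = c(height, width, dm[3L]))
  for (k in seq_len(dm[3L])) out[, , k] <- one_plane(img[, , k])
  out
}
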