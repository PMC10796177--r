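#' Colour signatures of the pseudo-histology renderer
#'
#' The synthetic slides are drawn with fixed, documented per-class colours so
#' that the deterministic reference backend can recover every planted object
#' by colour rules plus shape rules. The palettes are not photorealistic; they
#' are chosen pairwise well-separated (max channel distance >= 50 between any
#' two rule colours) so bilinear-resampling blends never match the wrong
#' class, while keeping every tissue colour darker than the white glass
#' background so Otsu foreground gating is meaningful.
#'
#' @return named list of RGB triplets (0..255).
#' @export
he_palette <- function() {
  list(
    background = c(255L, 255L, 255L),
    tissue     = c(230L, 205L, 215L),
    capsule    = c(120L, 60L, 140L),   # Bowman's capsule ring
    bowman     = c(185L, 215L, 235L),  # Bowman's space
    tuft       = c(200L, 120L, 170L),  # glomerular tuft
    crescent   = c(90L, 140L, 90L),    # crescent in Bowman's space
    wall       = c(240L, 150L, 90L),   # tubule / artery wall
    nucleus    = c(60L, 50L, 120L)
  )
}

#' @rdname he_palette
#' @export
pas_palette <- function() {
  list(
    background = c(255L, 255L, 255L),
    tissue     = c(235L, 220L, 210L),
    capsule    = c(140L, 80L, 150L),
    bowman     = c(235L, 228L, 232L),
    tuft       = c(215L, 160L, 185L),
    crescent   = c(120L, 150L, 110L),
    wall       = c(220L, 140L, 150L),
    mesangial  = c(150L, 40L, 100L),   # mesangial hypercellularity region
    endocap    = c(250L, 160L, 40L)    # endocapillary hypercellularity region
  )
}

# wall thickness as a fraction of the outer radius, per tubular class;
# the reference backend separates the classes on the measured fraction
wall_fractions <- function() c(artery = 0.55, proximal_tubule = 0.33, distal_tubule = 0.15)

#' Synthetic slide configuration
#'
#' Describes one synthetic slide triple: an H&E 10x raster (1 um/px), and
#' paired H&E and PAS 40x rasters (0.25 um/px) with exactly 4x the linear
#' dimensions. All geometry is generated on the 40x integer grid as multiples
#' of 4 and divided by 4 for 10x, so cross-magnification coordinates are
#' exact.
#'
#' @param seed integer; fully determines the output.
#' @param slide_width_10x,slide_height_10x 10x raster size in pixels; must be
#'   at least twice the maximum glomerulus diameter.
#' @param n_glomeruli,n_proximal,n_distal,n_arteries structure counts (>= 0).
#' @param crescent_fraction fraction of glomeruli given a crescent (exact
#'   count `round(fraction * n_glomeruli)`).
#' @param nuclei_per_tuft_range integer interval for the target number of
#'   nucleated cells planted per glomerular tuft (placement is collision-free;
#'   the achieved count is recorded in the ground truth).
#' @param mesangial_hyper_fraction,endocap_hyper_fraction fractions of
#'   glomeruli given a mesangial / endocapillary hypercellular region (each
#'   planted with >= 4 resp. >= 2 nuclei inside it).
#' @param glomerulus_radius_range_10x radius interval (pixels at 10x).
#' @param slide_id identifier stamped on rasters and annotations.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         slide_width_10x = 1024L, slide_height_10x = 1024L,
                         n_glomeruli = 12L, crescent_fraction = 0.25,
                         n_proximal = 10L, n_distal = 8L, n_arteries = 3L,
                         nuclei_per_tuft_range = c(8L, 18L),
                         mesangial_hyper_fraction = 0.25,
                         endocap_hyper_fraction = 0.25,
                         glomerulus_radius_range_10x = c(30L, 60L),
                         slide_id = sprintf("synth-%06d", seed)) {
  cfg <- list(
    seed = as.integer(seed),
    slide_width_10x = as.integer(slide_width_10x),
    slide_height_10x = as.integer(slide_height_10x),
    n_glomeruli = as.integer(n_glomeruli),
    crescent_fraction = crescent_fraction,
    n_proximal = as.integer(n_proximal),
    n_distal = as.integer(n_distal),
    n_arteries = as.integer(n_arteries),
    nuclei_per_tuft_range = as.integer(nuclei_per_tuft_range),
    mesangial_hyper_fraction = mesangial_hyper_fraction,
    endocap_hyper_fraction = endocap_hyper_fraction,
    glomerulus_radius_range_10x = as.integer(glomerulus_radius_range_10x),
    slide_id = as.character(slide_id)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c("n_glomeruli", "n_proximal", "n_distal", "n_arteries")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) stop("field ", f, " must be a count >= 0")
  }
  for (f in c("crescent_fraction", "mesangial_hyper_fraction", "endocap_hyper_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      stop("field ", f, " must lie in [0, 1]")
    }
  }
  rr <- cfg$glomerulus_radius_range_10x
  if (length(rr) != 2L || any(rr < 20L) || rr[1L] > rr[2L]) {
    stop("field glomerulus_radius_range_10x must be an increasing interval with minimum >= 20")
  }
  nr <- cfg$nuclei_per_tuft_range
  if (length(nr) != 2L || any(nr < 0L) || nr[1L] > nr[2L]) {
    stop("field nuclei_per_tuft_range must be a non-negative increasing interval")
  }
  if (min(cfg$slide_width_10x, cfg$slide_height_10x) < 4L * rr[2L]) {
    stop("field slide_width_10x/slide_height_10x: slide dimensions must be at ",
         "least twice the maximum glomerulus diameter (", 4L * rr[2L], " px)")
  }
  invisible(cfg)
}

# --- polygon builders (10x coordinates snapped to the 40x grid / 4) ---------

regular_poly <- function(cx, cy, r, k = 48L, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  cbind(x = round(cx + r * cos(th)), y = round(cy + r * sin(th)))
}

ellipse_poly <- function(cx, cy, a, b, theta, k = 20L) {
  t <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  ex <- a * cos(t); ey <- b * sin(t)
  cbind(
    x = round(cx + ex * cos(theta) - ey * sin(theta)),
    y = round(cy + ex * sin(theta) + ey * cos(theta))
  )
}

annulus_sector_poly <- function(cx, cy, r_in, r_out, th0, span, k = 24L) {
  th <- seq(th0, th0 + span, length.out = k)
  outer_arc <- cbind(cx + r_out * cos(th), cy + r_out * sin(th))
  inner_arc <- cbind(cx + r_in * cos(rev(th)), cy + r_in * sin(rev(th)))
  p <- rbind(outer_arc, inner_arc)
  cbind(x = round(p[, 1L]), y = round(p[, 2L]))
}

dedupe_poly <- function(p) {
  keep <- c(TRUE, rowSums(abs(diff(p))) > 0)
  p[keep, , drop = FALSE]
}

# linear indices (into an H x W matrix) of the pixels covered by a polygon
poly_pixels <- function(poly, W, H) {
  bb <- poly_bbox(poly)
  x0 <- max(0L, floor(bb[1L]) - 1L); y0 <- max(0L, floor(bb[2L]) - 1L)
  x1 <- min(W, ceiling(bb[1L] + bb[3L]) + 1L)
  y1 <- min(H, ceiling(bb[2L] + bb[4L]) + 1L)
  if (x1 <= x0 || y1 <= y0) return(integer(0))
  local <- poly
  local[, 1L] <- local[, 1L] - x0
  local[, 2L] <- local[, 2L] - y0
  m <- rasterize_polygon(local, x1 - x0, y1 - y0)
  idx <- which(m)
  if (!length(idx)) return(integer(0))
  h <- y1 - y0
  rr <- (idx - 1L) %% h + y0 + 1L
  cc <- (idx - 1L) %/% h + x0
  rr + cc * H
}

# rasterise a z-ordered list of (poly, col) ops onto a white canvas; painting
# happens channel-wise into matrices that stay local, so fills are in place
render_ops <- function(W, H, ops) {
  Rm <- matrix(255L, H, W); Gm <- matrix(255L, H, W); Bm <- matrix(255L, H, W)
  for (op in ops) {
    idx <- poly_pixels(op$poly, W, H)
    if (!length(idx)) next
    Rm[idx] <- op$col[1L]; Gm[idx] <- op$col[2L]; Bm[idx] <- op$col[3L]
  }
  arr <- array(0L, dim = c(H, W, 3L))
  arr[, , 1L] <- Rm; arr[, , 2L] <- Gm; arr[, , 3L] <- Bm
  arr
}

# rejection-sample a non-overlapping disk centre
place_disk <- function(w, h, r, placed, margin = 6, attempts = 400L) {
  rmax_place <- 0.40 * min(w, h) - r - 8
  if (rmax_place <= 0) stop("structure radius ", r, " too large for slide")
  cx0 <- w / 2; cy0 <- h / 2
  for (i in seq_len(attempts)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- rmax_place * sqrt(stats::runif(1))
    cx <- round(cx0 + rad * cos(ang)); cy <- round(cy0 + rad * sin(ang))
    ok <- TRUE
    if (nrow(placed)) {
      d <- sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2)
      ok <- all(d >= placed$r + r + margin)
    }
    if (ok) return(c(cx = cx, cy = cy))
  }
  stop("could not place a structure of radius ", r,
       "; reduce structure counts or enlarge the slide")
}

# place k points in a disk (centre cx/cy, radius rad) pairwise >= mind apart,
# optionally excluding disks given as data.frame(cx, cy, r)
place_points <- function(k, cx, cy, rad, mind, exclude = NULL, attempts = 250L) {
  pts <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(k)) {
    done <- FALSE
    for (a in seq_len(attempts)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- rad * sqrt(stats::runif(1))
      px <- round(cx + rr * cos(ang)); py <- round(cy + rr * sin(ang))
      if (nrow(pts) && any(sqrt((pts[, 1L] - px)^2 + (pts[, 2L] - py)^2) < mind)) next
      if (!is.null(exclude) && nrow(exclude) &&
          any(sqrt((exclude$cx - px)^2 + (exclude$cy - py)^2) < exclude$r)) next
      pts <- rbind(pts, c(px, py))
      done <- TRUE
      break
    }
    if (!done) break # best effort; achieved count is recorded
  }
  pts
}

#' Generate one paired synthetic slide triple with ground truth
#'
#' Renders an H&E 10x raster plus paired H&E and PAS 40x rasters of the same
#' pseudo-tissue (40x rasters have exactly 4x the linear dimensions) and
#' returns exhaustive ground truth: one instance per planted object, with
#' structures in 10x coordinates and nuclei/hypercellularity regions in 40x
#' coordinates. The same configuration always yields byte-identical rasters
#' and identical ground truth.
#'
#' @param config a [synth_config()].
#' @param render subset of `c("he10", "he40", "pas40")` to rasterise (the
#'   ground truth is always produced; skipping rasters saves time and memory
#'   in tests that only need a subset of the pipeline).
#' @return list of class `synth_slide_pair` with fields `he10`, `he40`,
#'   `pas40` ([slide_image()] or `NULL`), `ground_truth` and `config`.
#' @export
generate_slide_pair <- function(config, render = c("he10", "he40", "pas40")) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  if (length(render)) render <- match.arg(render, several.ok = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  w <- config$slide_width_10x; h <- config$slide_height_10x
  wf <- wall_fractions()

  # irregular tissue blob (single connected polygon), darker than background
  kt <- 28L
  tha <- seq(0, 2 * pi, length.out = kt + 1L)[-(kt + 1L)]
  trad <- stats::runif(kt, 0.41, 0.48) * min(w, h)
  tissue10 <- dedupe_poly(cbind(
    x = round(w / 2 + trad * cos(tha)),
    y = round(h / 2 + trad * sin(tha))
  ))

  placed <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))

  # glomeruli, largest first (helps packing)
  rr <- config$glomerulus_radius_range_10x
  grad <- sort(round(stats::runif(config$n_glomeruli, rr[1L], rr[2L])), decreasing = TRUE)
  gloms <- vector("list", config$n_glomeruli)
  for (i in seq_len(config$n_glomeruli)) {
    ctr <- place_disk(w, h, grad[i], placed)
    placed <- rbind(placed, data.frame(cx = ctr[1L], cy = ctr[2L], r = grad[i]))
    tc <- max(4L, round(0.12 * grad[i]))
    gloms[[i]] <- list(
      cx = ctr[1L], cy = ctr[2L], r = grad[i], tc = tc,
      ri = grad[i] - tc, rt = round(0.62 * grad[i])
    )
  }
  k_cres <- round(config$crescent_fraction * config$n_glomeruli)
  cres_ids <- if (k_cres > 0) sample(seq_len(config$n_glomeruli), k_cres) else integer(0)
  k_mes <- round(config$mesangial_hyper_fraction * config$n_glomeruli)
  mes_ids <- if (k_mes > 0) sample(seq_len(config$n_glomeruli), k_mes) else integer(0)
  k_endo <- round(config$endocap_hyper_fraction * config$n_glomeruli)
  endo_ids <- if (k_endo > 0) sample(seq_len(config$n_glomeruli), k_endo) else integer(0)

  # tubules and arteries: same wall colour, separated by wall thickness
  tubules <- list()
  tub_spec <- rbind(
    data.frame(label = rep("artery", config$n_arteries), rmin = 20, rmax = 30),
    data.frame(label = rep("proximal_tubule", config$n_proximal), rmin = 16, rmax = 26),
    data.frame(label = rep("distal_tubule", config$n_distal), rmin = 18, rmax = 28)
  )
  for (i in seq_len(nrow(tub_spec))) {
    r <- round(stats::runif(1, tub_spec$rmin[i], tub_spec$rmax[i]))
    ctr <- place_disk(w, h, r, placed)
    placed <- rbind(placed, data.frame(cx = ctr[1L], cy = ctr[2L], r = r))
    lab <- tub_spec$label[i]
    tubules[[length(tubules) + 1L]] <- list(
      label = lab, cx = ctr[1L], cy = ctr[2L], r = r,
      wt = max(2L, round(wf[[lab]] * r))
    )
  }

  # crescents (10x polygons), hyper regions and nuclei (40x)
  per_glom <- vector("list", length(gloms))
  for (i in seq_along(gloms)) {
    g <- gloms[[i]]
    crescent <- i %in% cres_ids
    if (crescent) {
      span <- stats::runif(1, 1.9, 3.4)
      th0 <- stats::runif(1, 0, 2 * pi)
      g$crescent_poly <- dedupe_poly(
        annulus_sector_poly(g$cx, g$cy, g$rt + 1, g$ri - 1, th0, span)
      )
    }
    cx40 <- g$cx * 4; cy40 <- g$cy * 4; rt40 <- g$rt * 4
    regions <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
    nuc_polys <- list(); nuc_ctr <- matrix(numeric(0), ncol = 2L)
    n_mes_nuc <- 0L; n_endo_nuc <- 0L
    base_ang <- stats::runif(1, 0, 2 * pi)
    if (i %in% mes_ids) {
      rm_ <- round(0.45 * rt40); dm <- round(0.42 * rt40)
      mx <- round(cx40 + dm * cos(base_ang)); my <- round(cy40 + dm * sin(base_ang))
      g$mes_poly <- regular_poly(mx, my, rm_, 32L)
      regions <- rbind(regions, data.frame(cx = mx, cy = my, r = rm_))
      nm <- sample(4:5, 1L)
      pts <- place_points(nm, mx, my, rm_ - 11, mind = 20)
      for (p in seq_len(nrow(pts))) {
        nuc_polys[[length(nuc_polys) + 1L]] <- dedupe_poly(ellipse_poly(
          pts[p, 1L], pts[p, 2L], stats::runif(1, 7.5, 8.5), stats::runif(1, 5, 6),
          stats::runif(1, 0, pi)
        ))
      }
      nuc_ctr <- rbind(nuc_ctr, pts)
      n_mes_nuc <- nrow(pts)
      g$mes_center <- c(mx, my); g$mes_r <- rm_
    }
    if (i %in% endo_ids) {
      re_ <- round(0.30 * rt40); de <- round(0.46 * rt40)
      ex <- round(cx40 + de * cos(base_ang + pi)); ey <- round(cy40 + de * sin(base_ang + pi))
      g$endo_poly <- regular_poly(ex, ey, re_, 32L)
      regions <- rbind(regions, data.frame(cx = ex, cy = ey, r = re_))
      ne <- sample(2:3, 1L)
      pts <- place_points(ne, ex, ey, re_ - 10, mind = 19)
      for (p in seq_len(nrow(pts))) {
        nuc_polys[[length(nuc_polys) + 1L]] <- dedupe_poly(ellipse_poly(
          pts[p, 1L], pts[p, 2L], stats::runif(1, 7, 8), stats::runif(1, 5, 6),
          stats::runif(1, 0, pi)
        ))
      }
      nuc_ctr <- rbind(nuc_ctr, pts)
      n_endo_nuc <- nrow(pts)
      g$endo_center <- c(ex, ey); g$endo_r <- re_
    }
    # remaining tuft nuclei, clear of the hyper regions
    m_target <- sample(seq(config$nuclei_per_tuft_range[1L],
                           config$nuclei_per_tuft_range[2L]), 1L)
    m_rest <- max(0L, m_target - nrow(nuc_ctr))
    excl <- if (nrow(regions)) {
      transform(regions, r = r + 16) # keep centroids clearly outside regions
    } else NULL
    if (m_rest > 0L) {
      pts <- place_points_away(m_rest, cx40, cy40, rt40 - 16, mind = 28,
                               exclude = excl, existing = nuc_ctr)
      for (p in seq_len(nrow(pts))) {
        nuc_polys[[length(nuc_polys) + 1L]] <- dedupe_poly(ellipse_poly(
          pts[p, 1L], pts[p, 2L], stats::runif(1, 9, 11.5), stats::runif(1, 6, 8),
          stats::runif(1, 0, pi)
        ))
      }
      nuc_ctr <- rbind(nuc_ctr, pts)
    }
    g$nuclei <- nuc_polys
    g$nuclei_centers <- nuc_ctr
    per_glom[[i]] <- data.frame(
      glom_id = i, cx_10x = g$cx, cy_10x = g$cy, radius_10x = g$r,
      tuft_radius_10x = g$rt, crescent = crescent,
      n_nuclei_tuft = length(nuc_polys),
      # flags reflect the achieved (planted) counts against the >=4 / >=2 rule
      mesangial_hyper = n_mes_nuc >= 4L, endocap_hyper = n_endo_nuc >= 2L,
      n_nuclei_mesangial = n_mes_nuc, n_nuclei_endocap = n_endo_nuc
    )
    gloms[[i]] <- g
  }

  gt <- build_ground_truth(config, gloms, tubules, per_glom)

  out <- list(he10 = NULL, he40 = NULL, pas40 = NULL,
              ground_truth = gt, config = config)
  if ("he10" %in% render) {
    out$he10 <- slide_image(
      render_he(w, h, 1L, tissue10, gloms, tubules, with_nuclei = FALSE),
      "HE", "10x", config$slide_id
    )
  }
  if ("he40" %in% render) {
    out$he40 <- slide_image(
      render_he(w * 4L, h * 4L, 4L, tissue10, gloms, tubules, with_nuclei = TRUE),
      "HE", "40x", config$slide_id
    )
  }
  if ("pas40" %in% render) {
    out$pas40 <- slide_image(
      render_pas(w * 4L, h * 4L, 4L, tissue10, gloms, tubules),
      "PAS", "40x", config$slide_id
    )
  }
  class(out) <- "synth_slide_pair"
  out
}

# like place_points but with pre-existing points to stay clear of
place_points_away <- function(k, cx, cy, rad, mind, exclude = NULL,
                              existing = NULL, attempts = 250L) {
  pts <- matrix(numeric(0), ncol = 2L)
  all_pts <- if (!is.null(existing) && nrow(existing)) existing else matrix(numeric(0), ncol = 2L)
  for (i in seq_len(k)) {
    done <- FALSE
    for (a in seq_len(attempts)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- rad * sqrt(stats::runif(1))
      px <- round(cx + rr * cos(ang)); py <- round(cy + rr * sin(ang))
      if (nrow(all_pts) &&
          any(sqrt((all_pts[, 1L] - px)^2 + (all_pts[, 2L] - py)^2) < mind)) next
      if (!is.null(exclude) && nrow(exclude) &&
          any(sqrt((exclude$cx - px)^2 + (exclude$cy - py)^2) < exclude$r)) next
      pts <- rbind(pts, c(px, py))
      all_pts <- rbind(all_pts, c(px, py))
      done <- TRUE
      break
    }
    if (!done) break
  }
  pts
}

scale_poly <- function(p, f) {
  p[, 1L] <- p[, 1L] * f
  p[, 2L] <- p[, 2L] * f
  p
}

render_he <- function(W, H, f, tissue10, gloms, tubules, with_nuclei) {
  pal <- he_palette()
  ops <- list(list(poly = scale_poly(tissue10, f), col = pal$tissue))
  for (tb in tubules) {
    ops <- c(ops, list(
      list(poly = regular_poly(tb$cx * f, tb$cy * f, tb$r * f), col = pal$wall),
      list(poly = regular_poly(tb$cx * f, tb$cy * f, (tb$r - tb$wt) * f),
           col = pal$tissue)
    ))
  }
  for (g in gloms) {
    ops <- c(ops, list(
      list(poly = regular_poly(g$cx * f, g$cy * f, g$r * f), col = pal$capsule),
      list(poly = regular_poly(g$cx * f, g$cy * f, g$ri * f), col = pal$bowman),
      list(poly = regular_poly(g$cx * f, g$cy * f, g$rt * f), col = pal$tuft)
    ))
    if (!is.null(g$crescent_poly)) {
      ops <- c(ops, list(list(poly = scale_poly(g$crescent_poly, f),
                              col = pal$crescent)))
    }
    if (with_nuclei && f == 4L) {
      for (np in g$nuclei) ops <- c(ops, list(list(poly = np, col = pal$nucleus)))
    }
  }
  render_ops(W, H, ops)
}

render_pas <- function(W, H, f, tissue10, gloms, tubules) {
  pal <- pas_palette()
  ops <- list(list(poly = scale_poly(tissue10, f), col = pal$tissue))
  for (tb in tubules) {
    ops <- c(ops, list(
      list(poly = regular_poly(tb$cx * f, tb$cy * f, tb$r * f), col = pal$wall),
      list(poly = regular_poly(tb$cx * f, tb$cy * f, (tb$r - tb$wt) * f),
           col = pal$tissue)
    ))
  }
  for (g in gloms) {
    ops <- c(ops, list(
      list(poly = regular_poly(g$cx * f, g$cy * f, g$r * f), col = pal$capsule),
      list(poly = regular_poly(g$cx * f, g$cy * f, g$ri * f), col = pal$bowman),
      list(poly = regular_poly(g$cx * f, g$cy * f, g$rt * f), col = pal$tuft)
    ))
    if (!is.null(g$crescent_poly)) {
      ops <- c(ops, list(list(poly = scale_poly(g$crescent_poly, f),
                              col = pal$crescent)))
    }
    if (!is.null(g$mes_poly)) {
      ops <- c(ops, list(list(poly = g$mes_poly, col = pal$mesangial)))
    }
    if (!is.null(g$endo_poly)) {
      ops <- c(ops, list(list(poly = g$endo_poly, col = pal$endocap)))
    }
  }
  render_ops(W, H, ops)
}

build_ground_truth <- function(config, gloms, tubules, per_glom) {
  sid <- config$slide_id
  structures <- list()
  for (i in seq_along(gloms)) {
    g <- gloms[[i]]
    lab <- if (per_glom[[i]]$crescent) "glomerulus_crescent" else "glomerulus_no_crescent"
    structures[[length(structures) + 1L]] <- wsi_instance(
      lab, regular_poly(g$cx, g$cy, g$r), slide_id = sid, magnification = "10x"
    )
    structures[[length(structures) + 1L]] <- wsi_instance(
      "glomerular_tuft", regular_poly(g$cx, g$cy, g$rt),
      slide_id = sid, magnification = "10x"
    )
  }
  for (tb in tubules) {
    structures[[length(structures) + 1L]] <- wsi_instance(
      tb$label, regular_poly(tb$cx, tb$cy, tb$r),
      slide_id = sid, magnification = "10x"
    )
  }
  nuclei <- list()
  regions <- list()
  for (g in gloms) {
    for (np in g$nuclei) {
      nuclei[[length(nuclei) + 1L]] <- wsi_instance(
        "nucleus", np, slide_id = sid, magnification = "40x"
      )
    }
    if (!is.null(g$mes_poly)) {
      regions[[length(regions) + 1L]] <- wsi_instance(
        "mesangial_hyper", g$mes_poly, slide_id = sid, magnification = "40x"
      )
    }
    if (!is.null(g$endo_poly)) {
      regions[[length(regions) + 1L]] <- wsi_instance(
        "endocap_hyper", g$endo_poly, slide_id = sid, magnification = "40x"
      )
    }
  }
  structure(
    list(
      slide_id = sid,
      structures = structures,  # 10x space
      nuclei = nuclei,          # 40x space
      regions = regions,        # 40x space
      per_glomerulus = do.call(rbind, per_glom)
    ),
    class = "wsi_ground_truth"
  )
}

#' Ground-truth instances at a chosen magnification
#'
#' Structures are stored at 10x; their 40x coordinates are exactly 4x.
#' Nuclei and hypercellularity regions exist at 40x only.
#'
#' @param gt a `wsi_ground_truth`.
#' @param magnification `"10x"` or `"40x"`.
#' @param labels optional label filter.
#' @return list of [wsi_instance()].
#' @export
gt_instances <- function(gt, magnification = c("10x", "40x"), labels = NULL) {
  magnification <- match.arg(magnification)
  out <- if (magnification == "10x") {
    gt$structures
  } else {
    c(lapply(gt$structures, function(i) {
      wsi_instance(i$label, scale_poly(i$polygon, 4), score = NULL,
                   slide_id = i$slide_id, magnification = "40x")
    }), gt$nuclei, gt$regions)
  }
  if (!is.null(labels)) {
    out <- Filter(function(i) i$label %in% labels, out)
  }
  out
}

#' Sampling rules for synthetic cohort metadata
#'
#' Ties per-slide metadata (age, sex, diagnosis) to the generator. When
#' `radius_scale_by_age` differs across the four age bins, planted glomerular
#' radii (hence areas) scale with the age group, enabling recovery tests of
#' the area-by-age analysis.
#'
#' @param radius_scale_by_age named numeric vector over the age bins
#'   `1-5, 6-10, 11-15, 16-20`.
#' @param age_sampler function(n) returning integer ages in 1..20.
#' @param diagnoses diagnosis vocabulary sampled uniformly.
#' @param n_glomeruli_sampler optional function(n) returning per-slide
#'   glomerulus counts (default `NULL`: every slide uses the base config's
#'   count; supply a sampler to vary counts across slides, e.g. for
#'   count-agreement harnesses).
#' @return object of class `cohort_metadata_spec`.
#' @export
cohort_metadata_spec <- function(
    radius_scale_by_age = c("1-5" = 1.0, "6-10" = 1.2, "11-15" = 1.4, "16-20" = 1.6),
    age_sampler = function(n) sample(1:20, n, replace = TRUE),
    diagnoses = c("IgAN", "MCD", "LN", "EPGN", "HSPN"),
    n_glomeruli_sampler = NULL) {
  stopifnot(setequal(names(radius_scale_by_age), age_bins()))
  structure(
    list(
      radius_scale_by_age = radius_scale_by_age,
      age_sampler = age_sampler, diagnoses = diagnoses,
      n_glomeruli_sampler = n_glomeruli_sampler
    ),
    class = "cohort_metadata_spec"
  )
}

#' Generate a reproducible synthetic cohort
#'
#' Draws per-slide metadata from `metadata_spec`, scales each slide's
#' glomerulus radius range by its age group, and generates one slide triple
#' per row. Rasters are rendered only for the stages in `render` (ground
#' truth is always produced) and optionally written to `out_dir` as PPM plus
#' GeoJSON; the cohort metadata table is written as CSV there too.
#'
#' @param config base [synth_config()]; `config$seed` seeds the cohort.
#' @param n_slides number of slides (>= 1).
#' @param metadata_spec a [cohort_metadata_spec()].
#' @param render passed to [generate_slide_pair()]; default renders nothing
#'   (callers regenerate rasters on demand from `slides[[i]]$config`).
#' @param out_dir optional output directory.
#' @return list with `slides` (each: `config`, `ground_truth`, and any
#'   rendered rasters), `metadata` (data.frame) and `planted` (per-slide
#'   planted glomerulus count and mean planted area in um^2 at 10x).
#' @export
generate_cohort <- function(config, n_slides, metadata_spec = cohort_metadata_spec(),
                            render = character(0), out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"), n_slides >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  ages <- metadata_spec$age_sampler(n_slides)
  groups <- age_group(ages)
  sexes <- sample(c("F", "M"), n_slides, replace = TRUE)
  diags <- sample(metadata_spec$diagnoses, n_slides, replace = TRUE)
  n_gloms <- if (is.null(metadata_spec$n_glomeruli_sampler)) {
    rep(config$n_glomeruli, n_slides)
  } else {
    metadata_spec$n_glomeruli_sampler(n_slides)
  }
  seeds <- (config$seed + 7919L * seq_len(n_slides)) %% 2147483647L

  slides <- vector("list", n_slides)
  planted <- vector("list", n_slides)
  meta <- data.frame(
    slide_id = sprintf("%s-%03d", config$slide_id, seq_len(n_slides)),
    age = ages, age_group = as.character(groups), sex = sexes, diagnosis = diags,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_slides)) {
    sc <- metadata_spec$radius_scale_by_age[[as.character(groups[i])]]
    cfg_i <- config
    cfg_i$seed <- as.integer(seeds[i])
    cfg_i$glomerulus_radius_range_10x <-
      as.integer(round(config$glomerulus_radius_range_10x * sc))
    cfg_i$n_glomeruli <- as.integer(n_gloms[i])
    cfg_i$slide_id <- meta$slide_id[i]
    class(cfg_i) <- "synth_config"
    validate_synth_config(cfg_i)
    sp <- generate_slide_pair(cfg_i, render = render)
    gt <- sp$ground_truth
    glom_polys <- Filter(function(x) x$label %in% glomerulus_labels(), gt$structures)
    areas <- vapply(glom_polys, function(x) poly_area(x$polygon), 0) * mpp_for("10x")^2
    planted[[i]] <- data.frame(
      slide_id = meta$slide_id[i],
      n_glomeruli = length(glom_polys),
      mean_glom_area_um2 = mean(areas)
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in intersect(render, c("he10", "he40", "pas40"))) {
        if (!is.null(sp[[nm]])) {
          write_ppm(sp[[nm]], file.path(out_dir, sprintf("%s_%s.ppm", meta$slide_id[i], nm)))
        }
      }
      write_annotations(
        annotation_set(gt$structures, meta$slide_id[i], "10x", "HE"),
        file.path(out_dir, sprintf("%s_structures.geojson", meta$slide_id[i]))
      )
    }
    slides[[i]] <- list(config = cfg_i, ground_truth = gt,
                        he10 = sp$he10, he40 = sp$he40, pas40 = sp$pas40)
  }
  planted <- do.call(rbind, planted)
  if (!is.null(out_dir)) {
    utils::write.csv(meta, file.path(out_dir, "cohort_metadata.csv"), row.names = FALSE)
  }
  list(slides = slides, metadata = meta, planted = planted)
}
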