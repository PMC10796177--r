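#' Per-patch segmentation backend contract
#'
#' A backend is the pluggable slot that a trained deep model (structure
#' segmentation, nuclei segmentation, hypercellularity segmentation) would
#' fill in production. It declares which (stain, magnification) pairs it
#' accepts and which labels it may emit, and maps a model-ready patch to a
#' list of scored instances in patch coordinates. The shipped reference
#' backends are deterministic colour-and-shape rule systems tied to the
#' synthetic renderer's documented palette; same patch, same output.
#'
#' @param name backend name.
#' @param accepts list of `c(stain, magnification)` pairs.
#' @param labels labels the backend may emit (subset of [wsi_labels()]).
#' @param fn `function(patch)` returning a list of [wsi_instance()].
#' @return object of class `wsi_backend`.
#' @export
wsi_backend <- function(name, accepts, labels, fn) {
  stopifnot(all(labels %in% wsi_labels()), is.function(fn))
  structure(
    list(name = name, accepts = accepts, labels = labels, fn = fn),
    class = "wsi_backend"
  )
}

backend_accepts <- function(backend, stain, magnification) {
  any(vapply(backend$accepts, function(p) {
    p[1L] == stain && p[2L] == magnification
  }, logical(1L)))
}

#' Run a backend on one patch
#'
#' Applies the backend after checking the (stain, magnification) pair and
#' filters detections below `score_threshold` (whether a score cut is applied
#' before whole-slide suppression is not fixed by the protocol; 0.05 is the
#' configurable default).
#'
#' @param patch H x W x 3 patch raster (model input space).
#' @param stain,magnification the patch's provenance.
#' @param backend a [wsi_backend()].
#' @param score_threshold minimum detection score kept.
#' @return list of scored [wsi_instance()] in patch coordinates.
#' @export
segment_patch <- function(patch, stain, magnification, backend,
                          score_threshold = 0.05) {
  stopifnot(inherits(backend, "wsi_backend"))
  if (!backend_accepts(backend, stain, magnification)) {
    pairs <- vapply(backend$accepts, paste, "", collapse = " ")
    stop(
      "backend '", backend$name, "' does not accept (", stain, ", ",
      magnification, "); accepted pairs: ", paste(pairs, collapse = ", ")
    )
  }
  out <- backend$fn(patch)
  Filter(function(i) !is.null(i$score) && i$score >= score_threshold, out)
}

# ---- colour rules -----------------------------------------------------------

# max-channel-distance colour match
match_color <- function(px, rgb, tol) {
  abs(px[, , 1L] - rgb[1L]) <= tol &
    abs(px[, , 2L] - rgb[2L]) <= tol &
    abs(px[, , 3L] - rgb[3L]) <= tol
}

# components of a colour rule, dropping small blobs and patch-border touchers
rule_components <- function(patch, rgb, tol, min_area = 30L, drop_border = TRUE) {
  m <- match_color(patch, rgb, tol)
  if (!any(m)) return(list(labels = NULL, ids = integer(0)))
  lab <- label_components(m, 8L)
  n <- attr(lab, "n")
  if (n == 0L) return(list(labels = NULL, ids = integer(0)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  ids <- which(sizes >= min_area)
  if (drop_border && length(ids)) {
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    ids <- setdiff(ids, border[border > 0L])
  }
  list(labels = lab, ids = ids, sizes = sizes)
}

component_instances <- function(comp, label, magnification, min_area = 30L) {
  out <- list()
  for (id in comp$ids) {
    poly <- component_polygon(comp$labels, id)
    # score: fraction of component pixels matching the class colour rule
    # (1 by construction for the rule backend; kept for the contract)
    out[[length(out) + 1L]] <- wsi_instance(
      label, poly, score = 1.0, magnification = magnification
    )
  }
  out
}

# wall-thickness fraction of a ring component: ring pixel count vs area
# enclosed by the traced outer boundary; theta = 1 - r_in/r_out for an annulus
ring_thickness_fraction <- function(ring_px, filled_area) {
  if (filled_area <= 0) return(1)
  1 - sqrt(max(0, 1 - ring_px / filled_area))
}

#' Reference backends for the synthetic palette
#'
#' Three deterministic rule backends mirroring the pipeline's three model
#' slots:
#' * `backend_reference_structures()` (H&E 10x): capsule-ring components
#'   become glomeruli (emitted as `glomerulus_no_crescent`; the crescent
#'   classifier refines the label downstream), tuft components become
#'   `glomerular_tuft`, wall-ring components are split into artery /
#'   proximal / distal tubule by measured wall-thickness fraction
#'   (>= 0.45 artery, >= 0.24 proximal, else distal; planted fractions are
#'   0.55 / 0.33 / 0.15).
#' * `backend_reference_nuclei()` (H&E 40x): nucleus-colour components.
#' * `backend_reference_pas()` (PAS 40x): mesangial / endocapillary region
#'   colour components.
#'
#' Components touching the patch border are dropped; with stride n/2 every
#' object of diameter <= stride is fully contained in some tile, so border
#' drops cost no recall after whole-slide fusion while preventing partial
#' duplicates.
#'
#' @return a [wsi_backend()].
#' @export
backend_reference_structures <- function() {
  pal <- he_palette()
  wsi_backend(
    name = "reference-structures",
    accepts = list(c("HE", "10x")),
    labels = c("glomerulus_no_crescent", "glomerulus_crescent",
               "glomerular_tuft", "artery", "proximal_tubule", "distal_tubule"),
    fn = function(patch) {
      out <- list()
      caps <- rule_components(patch, pal$capsule, tol = 45)
      for (id in caps$ids) {
        poly <- component_polygon(caps$labels, id)
        out[[length(out) + 1L]] <- wsi_instance(
          "glomerulus_no_crescent", poly, score = 1.0, magnification = "10x"
        )
      }
      tufts <- rule_components(patch, pal$tuft, tol = 25)
      out <- c(out, component_instances(tufts, "glomerular_tuft", "10x"))
      walls <- rule_components(patch, pal$wall, tol = 45)
      for (id in walls$ids) {
        poly <- component_polygon(walls$labels, id)
        theta <- ring_thickness_fraction(walls$sizes[id], poly_area(poly))
        lab <- if (theta >= 0.45) "artery" else if (theta >= 0.24) {
          "proximal_tubule"
        } else "distal_tubule"
        out[[length(out) + 1L]] <- wsi_instance(
          lab, poly, score = 1.0, magnification = "10x"
        )
      }
      out
    }
  )
}

#' @rdname backend_reference_structures
#' @export
backend_reference_nuclei <- function() {
  pal <- he_palette()
  wsi_backend(
    name = "reference-nuclei",
    accepts = list(c("HE", "40x")),
    labels = "nucleus",
    fn = function(patch) {
      comp <- rule_components(patch, pal$nucleus, tol = 40, min_area = 8L)
      component_instances(comp, "nucleus", "40x", min_area = 8L)
    }
  )
}

#' @rdname backend_reference_structures
#' @export
backend_reference_pas <- function() {
  pal <- pas_palette()
  wsi_backend(
    name = "reference-pas",
    accepts = list(c("PAS", "40x")),
    labels = c("mesangial_hyper", "endocap_hyper"),
    fn = function(patch) {
      mes <- rule_components(patch, pal$mesangial, tol = 30)
      endo <- rule_components(patch, pal$endocap, tol = 30)
      c(
        component_instances(mes, "mesangial_hyper", "40x"),
        component_instances(endo, "endocap_hyper", "40x")
      )
    }
  )
}

#' Simulate an imperfect backend by random detection dropout
#'
#' Wraps a backend so each emitted instance is independently discarded with
#' probability `rate` (deterministic given `seed`); used to verify that
#' agreement statistics strictly degrade when the detector degrades.
#'
#' @param backend a [wsi_backend()].
#' @param rate dropout probability in [0, 1).
#' @param seed seed for the wrapper's private RNG stream.
#' @return a [wsi_backend()].
#' @export
backend_dropout <- function(backend, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  state <- new.env(parent = emptyenv())
  state$counter <- 0L
  wsi_backend(
    name = paste0(backend$name, "-dropout", rate),
    accepts = backend$accepts,
    labels = backend$labels,
    fn = function(patch) {
      out <- backend$fn(patch)
      if (!length(out)) return(out)
      state$counter <- state$counter + 1L
      keep <- withr_rng(seed + state$counter, function() {
        stats::runif(length(out)) >= rate
      })
      out[keep]
    }
  )
}

# evaluate fn under a temporary RNG state
withr_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Crop a glomerulus for crescent classification
#'
#' Crops the instance's bounding box from the H&E 10x slide (clipped to the
#' slide if needed), pads right/bottom with `pad_value` to a square, and
#' resizes to 224 x 224 — the input contract of the crescent classifier.
#' Aspect ratio is preserved by the square padding.
#'
#' @param slide the H&E 10x [slide_image()].
#' @param instance a glomerulus [wsi_instance()] in slide space.
#' @param pad_value fill for the square padding.
#' @return integer 224 x 224 x 3 array.
#' @export
crop_for_classification <- function(slide, instance, pad_value = 255) {
  stopifnot(inherits(slide, "slide_image"), inherits(instance, "wsi_instance"))
  if (!instance$label %in% glomerulus_labels()) {
    stop("instance label must be one of: ",
         paste(glomerulus_labels(), collapse = ", "))
  }
  dm <- dim(slide$pixels)
  bb <- instance$bbox
  x0 <- max(0L, floor(bb[1L])); y0 <- max(0L, floor(bb[2L]))
  x1 <- min(dm[2L], ceiling(bb[1L] + bb[3L])); y1 <- min(dm[1L], ceiling(bb[2L] + bb[4L]))
  if (x1 <= x0 || y1 <= y0) stop("instance bbox does not intersect the slide")
  crop <- slide$pixels[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]
  side <- max(dim(crop)[1L], dim(crop)[2L])
  sq <- array(pad_value, dim = c(side, side, 3L))
  sq[seq_len(dim(crop)[1L]), seq_len(dim(crop)[2L]), ] <- crop
  if (side == 224L) {
    out <- sq
  } else {
    out <- round(resize_bilinear(sq, 224L, 224L))
  }
  storage.mode(out) <- "integer"
  out[] <- pmin(255L, pmax(0L, out))
  out
}

#' Classify a glomerulus crop as crescentic or not
#'
#' The reference classifier measures the fraction `f` of the Bowman-space
#' annulus (pixels matching the Bowman or crescent colour signature) that
#' matches the crescent signature and scores `min(1, f / f0)` with the
#' documented constant `f0 = 0.2` (planted crescents span at least ~110
#' degrees of the annulus, i.e. f >= ~0.3). The label is `crescentic` iff the
#' score is >= 0.5; the score is the crescentic-class probability.
#'
#' @param crop integer 224 x 224 x 3 array from [crop_for_classification()].
#' @param f0 reference annulus fraction mapping to score 1.
#' @return list of class `crescent_call` with `label` and `score`.
#' @export
classify_crescent <- function(crop, f0 = 0.2) {
  dm <- dim(crop)
  if (length(dm) != 3L || dm[1L] != 224L || dm[2L] != 224L) {
    stop("crescent classifier input must be a 224 x 224 x 3 array")
  }
  pal <- he_palette()
  n_cres <- sum(match_color(crop, pal$crescent, 30))
  n_bow <- sum(match_color(crop, pal$bowman, 30))
  f <- if (n_cres + n_bow == 0L) 0 else n_cres / (n_cres + n_bow)
  score <- min(1, f / f0)
  structure(
    list(label = if (score >= 0.5) "crescentic" else "non_crescentic",
         score = score),
    class = "crescent_call"
  )
}
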