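#' Intersection over union of two boxes
#'
#' Boxes are `(x, y, w, h)` in the half-open convention
#' `[x, x+w) x [y, y+h)`; 0.5 is the matching and suppression threshold used
#' throughout the pipeline.
#'
#' @param a,b numeric `c(x, y, w, h)` with positive `w`, `h`.
#' @return IoU in [0, 1]; 0 when disjoint.
#' @export
iou <- function(a, b) {
  if (a[3L] <= 0 || a[4L] <= 0 || b[3L] <= 0 || b[4L] <= 0) {
    stop("boxes must have positive width and height")
  }
  ix <- min(a[1L] + a[3L], b[1L] + b[3L]) - max(a[1L], b[1L])
  iy <- min(a[2L] + a[4L], b[2L] + b[4L]) - max(a[2L], b[2L])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[3L] * a[4L] + b[3L] * b[4L] - inter)
}

# vectorised IoU of one box against a 4-column matrix of boxes
iou_many <- function(a, B) {
  ix <- pmin(a[1L] + a[3L], B[, 1L] + B[, 3L]) - pmax(a[1L], B[, 1L])
  iy <- pmin(a[2L] + a[4L], B[, 2L] + B[, 4L]) - pmax(a[2L], B[, 2L])
  inter <- pmax(ix, 0) * pmax(iy, 0)
  inter / (a[3L] * a[4L] + B[, 3L] * B[, 4L] - inter)
}

instance_boxes <- function(instances) {
  if (!length(instances)) return(matrix(numeric(0), ncol = 4L))
  t(vapply(instances, `[[`, numeric(4L), "bbox"))
}

#' Greedy non-maximum suppression
#'
#' Standard whole-slide suppression: sort by score descending (ties: larger
#' area first, then input order), keep the head, suppress every remaining
#' instance with IoU strictly greater than the threshold against a kept box.
#' Suppressed instances are discarded outright (no mask merging); the
#' operation is idempotent.
#'
#' @param instances list of scored [wsi_instance()] of one class.
#' @param iou_threshold suppression threshold (default 0.5); ties at exactly
#'   the threshold are kept.
#' @return the kept instances, in decreasing score order.
#' @export
nms <- function(instances, iou_threshold = 0.5) {
  if (!length(instances)) return(instances)
  labs <- unique(vapply(instances, `[[`, "", "label"))
  if (length(labs) > 1L) {
    stop("nms expects instances of a single class; got: ",
         paste(labs, collapse = ", "))
  }
  if (any(vapply(instances, function(i) is.null(i$score), logical(1L)))) {
    stop("all instances must carry a score for nms")
  }
  scores <- vapply(instances, `[[`, 0, "score")
  B <- instance_boxes(instances)
  areas <- B[, 3L] * B[, 4L]
  ord <- order(-scores, -areas, seq_along(instances))
  kept <- integer(0)
  alive <- rep(TRUE, length(instances))
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    over <- iou_many(B[i, ], B) > iou_threshold
    over[i] <- FALSE
    alive[over] <- FALSE
  }
  instances[kept]
}

#' Rescale instances between magnifications
#'
#' Multiplies every coordinate by `factor` (areas scale by `factor^2`): 1/4
#' maps 40x nuclei masks down to 10x structure space, 4 maps 10x boxes up to
#' 40x.
#'
#' @param instances list of [wsi_instance()].
#' @param factor positive scale factor.
#' @param magnification magnification tag for the rescaled space.
#' @return rescaled instances.
#' @export
rescale_instances <- function(instances, factor,
                              magnification = c("10x", "40x")) {
  stopifnot(factor > 0)
  magnification <- match.arg(magnification)
  lapply(instances, function(i) {
    wsi_instance(
      i$label, scale_poly(i$polygon, factor), score = i$score,
      slide_id = i$slide_id, magnification = magnification
    )
  })
}

#' Transfer glomerulus detections to the 40x PAS frame
#'
#' Multiplies detected 10x glomerulus coordinates `(x, y, w, h)` by 4 to
#' obtain the corresponding 40x PAS boxes used to crop hypercellularity
#' patches.
#'
#' @param instances glomerulus instances in 10x space.
#' @return the same instances in 40x coordinates.
#' @export
transfer_to_pas <- function(instances) {
  rescale_instances(instances, 4, magnification = "40x")
}

#' Assemble per-tile detections into a whole-slide result
#'
#' 1. maps every tile instance to slide coordinates through its recorded
#'    [patch_transform()]; 2. applies per-class NMS at IoU 0.5 in 10x slide
#'    space (per class: glomerulus detections never suppress tubules or the
#'    nested tufts); 3. maps nuclei tiles to 40x slide space, suppresses them
#'    at 40x, then rescales by 1/4; 4. assigns each nucleus to the structure
#'    containing its centroid, glomerular tuft taking precedence over the
#'    enclosing glomerulus, smaller structures over larger; unassigned nuclei
#'    are retained flagged `interstitial`.
#'
#' @param structure_tiles list of `list(instances=, transform=)` pairs from
#'   the H&E 10x route.
#' @param nuclei_tiles list of `list(instances=, transform=)` pairs from the
#'   H&E 40x route.
#' @param slide_id slide identifier; all transforms must come from this slide.
#' @param iou_threshold NMS threshold.
#' @return object of class `whole_slide_result` with `structures` (10x),
#'   `nuclei_40x`, `nuclei_10x`, and `assignment` (data.frame).
#' @export
assemble_slide <- function(structure_tiles, nuclei_tiles = list(),
                           slide_id = NA_character_, iou_threshold = 0.5) {
  map_tiles <- function(tiles) {
    out <- list()
    for (tl in tiles) {
      for (inst in tl$instances) {
        if (!is.na(slide_id) && !is.na(inst$slide_id) &&
            nzchar(inst$slide_id) && inst$slide_id != slide_id &&
            inst$slide_id != "NA") {
          stop("instance slide_id ", inst$slide_id,
               " does not match assembly slide ", slide_id)
        }
        out[[length(out) + 1L]] <- to_slide_coords(inst, tl$transform, slide_id)
      }
    }
    out
  }
  structs <- map_tiles(structure_tiles)
  structs <- nms_by_class(structs, iou_threshold)
  nuc40 <- map_tiles(nuclei_tiles)
  nuc40 <- nms_by_class(nuc40, iou_threshold)
  nuc10 <- rescale_instances(nuc40, 1 / 4, magnification = "10x")
  assignment <- assign_nuclei(nuc10, structs)
  structure(
    list(
      slide_id = slide_id, structures = structs,
      nuclei_40x = nuc40, nuclei_10x = nuc10,
      assignment = assignment,
      regions_40x = list(), crescent_calls = NULL
    ),
    class = "whole_slide_result"
  )
}

nms_by_class <- function(instances, iou_threshold = 0.5) {
  if (!length(instances)) return(instances)
  labs <- vapply(instances, `[[`, "", "label")
  out <- list()
  for (lb in unique(labs)) {
    out <- c(out, nms(instances[labs == lb], iou_threshold))
  }
  out
}

# nucleus -> structure assignment by centroid containment; tuft first,
# then other structures smallest-area first; otherwise interstitial
assign_nuclei <- function(nuclei_10x, structures) {
  if (!length(nuclei_10x)) {
    return(data.frame(nucleus = integer(0), structure = integer(0),
                      structure_label = character(0)))
  }
  labs <- vapply(structures, `[[`, "", "label")
  areas <- vapply(structures, function(s) poly_area(s$polygon), 0)
  order_pref <- order(labs != "glomerular_tuft", areas)
  cent <- t(vapply(nuclei_10x, function(n) poly_centroid(n$polygon), numeric(2L)))
  assigned <- rep(NA_integer_, length(nuclei_10x))
  unresolved <- seq_along(nuclei_10x)
  for (si in order_pref) {
    if (!length(unresolved)) break
    inside <- point_in_polygon(cent[unresolved, 1L], cent[unresolved, 2L],
                               structures[[si]]$polygon)
    assigned[unresolved[inside]] <- si
    unresolved <- unresolved[!inside]
  }
  data.frame(
    nucleus = seq_along(nuclei_10x),
    structure = assigned,
    structure_label = ifelse(is.na(assigned), "interstitial", labs[assigned]),
    stringsAsFactors = FALSE
  )
}

#' Pipeline configuration
#'
#' @param score_threshold pre-NMS detection score cut (default 0.05).
#' @param iou_threshold NMS / matching threshold (default 0.5).
#' @param crescent_f0 reference crescent-classifier constant.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(score_threshold = 0.05, iou_threshold = 0.5,
                            crescent_f0 = 0.2) {
  structure(
    list(score_threshold = score_threshold, iou_threshold = iou_threshold,
         crescent_f0 = crescent_f0),
    class = "pipeline_config"
  )
}

#' Run the whole-slide pipeline on a slide triple
#'
#' Executes the full flow on one slide: Otsu-gated tiling of the H&E 10x
#' slide and per-patch structure segmentation; whole-slide assembly with
#' per-class NMS; crescent classification of every detected glomerulus from
#' 224 x 224 crops; Otsu-gated tiling of the H&E 40x slide for nuclei,
#' suppressed at 40x, rescaled 1/4 and integrated with the 10x structures;
#' transfer of glomerulus boxes (x4) onto the PAS 40x slide and
#' hypercellularity region segmentation within those crops; finally
#' per-glomerulus hypercellularity flags from the >= 4 mesangial / >= 2
#' endocapillary nucleus rules.
#'
#' @param he10,he40,pas40 [slide_image()] objects (later stages may be `NULL`
#'   if the corresponding stage is not requested).
#' @param backends named list with `structures`, `nuclei`, `pas` backends.
#' @param config a [pipeline_config()].
#' @param stages subset of `c("structures", "crescent", "nuclei", "pas")`.
#' @return a `whole_slide_result` with `structures` (labelled glomeruli after
#'   crescent classification), `nuclei_40x`/`nuclei_10x`, `assignment`,
#'   `regions_40x`, `crescent_calls` and `glomerulus_flags`.
#' @export
run_pipeline <- function(he10, he40 = NULL, pas40 = NULL,
                         backends = reference_backends(),
                         config = pipeline_config(),
                         stages = c("structures", "crescent", "nuclei", "pas")) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(inherits(he10, "slide_image"))
  slide_id <- he10$slide_id

  # --- H&E 10x structures ---
  tc10 <- tile_config_for("10x")
  plan <- plan_tiles(foreground_mask(he10), tc10)
  structure_tiles <- list()
  for (k in seq_len(nrow(plan))) {
    ex <- extract_patch(he10, c(plan$x0[k], plan$y0[k]), tc10)
    dets <- segment_patch(ex$patch, "HE", "10x", backends$structures,
                          config$score_threshold)
    structure_tiles[[k]] <- list(instances = dets, transform = ex$transform)
  }

  # --- H&E 40x nuclei ---
  nuclei_tiles <- list()
  if ("nuclei" %in% stages && !is.null(he40)) {
    tc40 <- tile_config_for("40x")
    plan40 <- plan_tiles(foreground_mask(he40), tc40)
    for (k in seq_len(nrow(plan40))) {
      ex <- extract_patch(he40, c(plan40$x0[k], plan40$y0[k]), tc40)
      dets <- segment_patch(ex$patch, "HE", "40x", backends$nuclei,
                            config$score_threshold)
      nuclei_tiles[[k]] <- list(instances = dets, transform = ex$transform)
    }
  }

  result <- assemble_slide(structure_tiles, nuclei_tiles, slide_id,
                           config$iou_threshold)

  # --- crescent classification of detected glomeruli ---
  if ("crescent" %in% stages) {
    labs <- vapply(result$structures, `[[`, "", "label")
    gidx <- which(labs %in% glomerulus_labels())
    calls <- vector("list", length(gidx))
    for (j in seq_along(gidx)) {
      inst <- result$structures[[gidx[j]]]
      crop <- crop_for_classification(he10, inst)
      call <- classify_crescent(crop, config$crescent_f0)
      calls[[j]] <- call
      new_label <- if (call$label == "crescentic") {
        "glomerulus_crescent"
      } else "glomerulus_no_crescent"
      result$structures[[gidx[j]]] <- wsi_instance(
        new_label, inst$polygon, score = inst$score,
        slide_id = inst$slide_id, magnification = inst$magnification
      )
    }
    result$crescent_calls <- calls
  }

  # --- PAS 40x hypercellularity within transferred glomerulus boxes ---
  if ("pas" %in% stages && !is.null(pas40)) {
    labs <- vapply(result$structures, `[[`, "", "label")
    gloms <- result$structures[labs %in% glomerulus_labels()]
    boxes40 <- transfer_to_pas(gloms)
    regions <- list()
    dm <- dim(pas40$pixels)
    for (g in boxes40) {
      bb <- g$bbox
      x0 <- max(0L, floor(bb[1L])); y0 <- max(0L, floor(bb[2L]))
      x1 <- min(dm[2L], ceiling(bb[1L] + bb[3L]))
      y1 <- min(dm[1L], ceiling(bb[2L] + bb[4L]))
      if (x1 <= x0 || y1 <= y0) next
      crop <- pas40$pixels[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]
      dets <- segment_patch(crop, "PAS", "40x", backends$pas,
                            config$score_threshold)
      tf <- patch_transform(x0 = x0, y0 = y0, n = x1 - x0, scale = 1)
      for (d in dets) {
        regions[[length(regions) + 1L]] <- to_slide_coords(d, tf, slide_id)
      }
    }
    result$regions_40x <- nms_by_class(regions, config$iou_threshold)
    result$glomerulus_flags <- glomerulus_hyper_flags(result)
  }
  result
}

#' @rdname run_pipeline
#' @export
reference_backends <- function() {
  list(
    structures = backend_reference_structures(),
    nuclei = backend_reference_nuclei(),
    pas = backend_reference_pas()
  )
}

#' @export
print.whole_slide_result <- function(x, ...) {
  labs <- vapply(x$structures, `[[`, "", "label")
  cat(sprintf("<whole_slide_result %s: %d structures, %d nuclei, %d regions>\n",
              x$slide_id, length(x$structures), length(x$nuclei_40x),
              length(x$regions_40x)))
  if (length(labs)) print(table(labs))
  invisible(x)
}

# per-glomerulus hypercellularity flags from detected regions and nuclei
glomerulus_hyper_flags <- function(result) {
  labs <- vapply(result$structures, `[[`, "", "label")
  gidx <- which(labs %in% glomerulus_labels())
  if (!length(gidx)) {
    return(data.frame(glomerulus = integer(0), mesangial_hyper = logical(0),
                      endocap_hyper = logical(0)))
  }
  nuc_cent <- if (length(result$nuclei_40x)) {
    t(vapply(result$nuclei_40x, function(n) poly_centroid(n$polygon), numeric(2L)))
  } else matrix(numeric(0), ncol = 2L)
  rlabs <- vapply(result$regions_40x, `[[`, "", "label")
  out <- lapply(seq_along(gidx), function(j) {
    g40 <- scale_poly(result$structures[[gidx[j]]]$polygon, 4)
    inside_glom <- if (nrow(nuc_cent)) {
      point_in_polygon(nuc_cent[, 1L], nuc_cent[, 2L], g40)
    } else logical(0)
    g_regions <- Filter(function(r) {
      point_in_polygon(poly_centroid(r$polygon)[1L], poly_centroid(r$polygon)[2L], g40)
    }, result$regions_40x)
    fl <- hypercellularity_flags(
      nuc_cent[inside_glom, , drop = FALSE],
      Filter(function(r) r$label == "mesangial_hyper", g_regions),
      Filter(function(r) r$label == "endocap_hyper", g_regions)
    )
    data.frame(glomerulus = gidx[j], mesangial_hyper = fl$mesangial,
               endocap_hyper = fl$endocap)
  })
  do.call(rbind, out)
}
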