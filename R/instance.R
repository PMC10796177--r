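#' Allowed annotation labels
#'
#' The nine object classes of the annotation scheme: five kidney structures
#' detected on H&E 10x (arteries, distal and proximal tubules, glomeruli with
#' and without crescents), the glomerular tuft, the two PAS 40x
#' hypercellularity region classes, and nuclei (H&E 40x).
#'
#' @return character vector of the nine allowed labels.
#' @export
wsi_labels <- function() {
  c(
    "artery", "distal_tubule", "proximal_tubule",
    "glomerulus_crescent", "glomerulus_no_crescent", "glomerular_tuft",
    "mesangial_hyper", "endocap_hyper", "nucleus"
  )
}

glomerulus_labels <- function() c("glomerulus_crescent", "glomerulus_no_crescent")

#' Annotated or detected object instance
#'
#' One object with class label, polygon outline, tight bounding box and an
#' optional detection score. Coordinates are 0-based pixels (x rightward, y
#' downward); the bbox `(x, y, w, h)` covers `[x, x+w) x [y, y+h)` and is
#' always the tight bounds of the polygon. Ground-truth instances carry no
#' score (`NULL`), detections carry a score in (0, 1].
#'
#' @param label one of [wsi_labels()].
#' @param polygon n x 2 matrix of (x, y) vertices, open ring.
#' @param score detection score in (0, 1] or `NULL` for ground truth.
#' @param slide_id,magnification the coordinate space of the polygon.
#' @return object of class `wsi_instance`.
#' @export
wsi_instance <- function(label, polygon, score = NULL, slide_id = NA_character_,
                         magnification = c("10x", "40x")) {
  if (!label %in% wsi_labels()) {
    stop(
      "unknown label '", label, "'; allowed labels are: ",
      paste(wsi_labels(), collapse = ", ")
    )
  }
  polygon <- as_polygon(polygon)
  bbox <- poly_bbox(polygon)
  if (bbox["w"] <= 0 || bbox["h"] <= 0) {
    stop("instance polygon has nonpositive extent (w, h must be > 0)")
  }
  if (!is.null(score)) {
    score <- as.numeric(score)
    if (!is.finite(score) || score < 0 || score > 1) {
      stop("score must lie in [0, 1]")
    }
  }
  structure(
    list(
      label = label, polygon = polygon, bbox = bbox, score = score,
      slide_id = as.character(slide_id),
      magnification = match.arg(magnification)
    ),
    class = "wsi_instance"
  )
}

#' @export
print.wsi_instance <- function(x, ...) {
  cat(sprintf(
    "<wsi_instance %s bbox=(%g,%g,%g,%g)%s>\n", x$label,
    x$bbox[1L], x$bbox[2L], x$bbox[3L], x$bbox[4L],
    if (is.null(x$score)) "" else sprintf(" score=%.3f", x$score)
  ))
  invisible(x)
}

#' Set of instances sharing one coordinate space
#'
#' @param instances list of [wsi_instance()] objects.
#' @param slide_id,magnification,stain the shared space.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(instances, slide_id = NA_character_,
                           magnification = c("10x", "40x"),
                           stain = c("HE", "PAS")) {
  magnification <- match.arg(magnification)
  stopifnot(is.list(instances))
  for (inst in instances) {
    if (!inherits(inst, "wsi_instance")) stop("instances must be wsi_instance objects")
    if (inst$magnification != magnification) {
      stop("instance magnification ", inst$magnification,
           " does not match set magnification ", magnification)
    }
  }
  structure(
    list(
      instances = instances, slide_id = as.character(slide_id),
      magnification = magnification, stain = match.arg(stain)
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  tab <- table(vapply(x$instances, `[[`, "", "label"))
  cat(sprintf(
    "<annotation_set %s %s %s: %d instances>\n",
    x$slide_id, x$stain, x$magnification, length(x$instances)
  ))
  if (length(tab)) print(tab)
  invisible(x)
}

#' Read and write instance annotations as GeoJSON
#'
#' Annotations interchange as a GeoJSON FeatureCollection (QuPath-compatible
#' dialect): every Feature is a Polygon whose `properties` carry `label` and
#' optionally `score`, `slide_id`, `magnification`. Round trips are lossless
#' for vertices, labels and scores; unknown labels and non-polygon geometries
#' are rejected.
#'
#' @param set an [annotation_set()].
#' @param path file path.
#' @return `read_annotations` returns an [annotation_set()].
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  feats <- lapply(set$instances, function(inst) {
    ring <- rbind(inst$polygon, inst$polygon[1L, , drop = FALSE])
    props <- list(
      objectType = "annotation",
      label = inst$label,
      slide_id = inst$slide_id,
      magnification = inst$magnification
    )
    if (!is.null(inst$score)) props$score <- inst$score
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) ring[i, ]))
      ),
      properties = props
    )
  })
  fc <- list(
    type = "FeatureCollection",
    properties = list(
      slide_id = set$slide_id, magnification = set$magnification,
      stain = set$stain
    ),
    features = feats
  )
  writeLines(
    jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null"),
    path
  )
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  meta <- fc$properties
  insts <- lapply(fc$features, function(f) {
    g <- f$geometry
    if (is.null(g$type) || g$type != "Polygon") {
      stop("only Polygon geometries are supported (got ",
           if (is.null(g$type)) "none" else g$type, ")")
    }
    ring <- g$coordinates[[1L]]
    poly <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    p <- f$properties
    if (is.null(p$label)) stop("feature missing 'label' property")
    wsi_instance(
      label = p$label, polygon = poly,
      score = if (is.null(p$score)) NULL else as.numeric(p$score),
      slide_id = if (is.null(p$slide_id)) NA_character_ else p$slide_id,
      magnification = if (is.null(p$magnification)) "10x" else p$magnification
    )
  })
  annotation_set(
    insts,
    slide_id = if (is.null(meta$slide_id)) NA_character_ else meta$slide_id,
    magnification = if (is.null(meta$magnification)) "10x" else meta$magnification,
    stain = if (is.null(meta$stain)) "HE" else meta$stain
  )
}

#' Rasterise an instance polygon and re-vectorise it
#'
#' Masks are the segmentation currency of the per-patch backends; this round
#' trip (pixel-centre rasterisation, crack-boundary re-vectorisation) is the
#' contract they rely on. For polygons of area >= 100 px the re-vectorised
#' area agrees with the polygon area within 2%.
#'
#' @param instance a [wsi_instance()].
#' @param extent `c(width, height)` of the raster.
#' @return list with `mask` (logical matrix) and `polygon` (re-traced ring).
#' @export
polygon_mask_roundtrip <- function(instance, extent) {
  stopifnot(inherits(instance, "wsi_instance"), length(extent) == 2L)
  bb <- instance$bbox
  if (bb[1L] < 0 || bb[2L] < 0 ||
      bb[1L] + bb[3L] > extent[1L] || bb[2L] + bb[4L] > extent[2L]) {
    stop("polygon lies outside the raster extent")
  }
  mask <- rasterize_polygon(instance$polygon, extent[1L], extent[2L])
  list(mask = mask, polygon = mask_to_polygon(mask))
}
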