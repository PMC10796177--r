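#' Morphometric record for one instance
#'
#' Physical-unit morphometry from the instance polygon: area (um^2),
#' perimeter (um), roundness defined as the isoperimetric ratio
#' `4 pi A / P^2` (1 for a disk, dimensionless, invariant to scale), major
#' axis length of the second-moment ellipse ("length", um), and the
#' equivalent circular diameter `2 sqrt(A / pi)` (um).
#'
#' @param instance a [wsi_instance()] with a non-degenerate polygon.
#' @param mpp microns per pixel of the instance's coordinate space.
#' @return one-row data.frame.
#' @export
morphometry <- function(instance, mpp) {
  stopifnot(inherits(instance, "wsi_instance"), mpp > 0)
  a_px <- poly_area(instance$polygon)
  if (a_px <= 0) stop("degenerate polygon: zero area")
  p_px <- poly_perimeter(instance$polygon)
  mom <- poly_moments(instance$polygon)
  area <- a_px * mpp^2
  perim <- p_px * mpp
  data.frame(
    label = instance$label,
    area_um2 = area,
    perimeter_um = perim,
    roundness = 4 * pi * area / perim^2,
    major_axis_um = mom$major_axis_length * mpp,
    equivalent_diameter_um = 2 * sqrt(area / pi),
    score = if (is.null(instance$score)) NA_real_ else instance$score,
    stringsAsFactors = FALSE
  )
}

#' Count glomeruli in a whole-slide result
#'
#' Number of assembled instances labelled `glomerulus_crescent` or
#' `glomerulus_no_crescent` (the headline counting output compared against
#' manual counts).
#'
#' @param result a `whole_slide_result`.
#' @return integer count.
#' @export
count_glomeruli <- function(result) {
  stopifnot(inherits(result, "whole_slide_result"))
  labs <- vapply(result$structures, `[[`, "", "label")
  sum(labs %in% glomerulus_labels())
}

#' Hypercellularity flags from nucleus centroids and detected regions
#'
#' Operational definitions: mesangial hypercellularity iff at least four
#' nucleus centroids fall inside a single detected mesangial region;
#' endocapillary hypercellularity iff at least two fall inside a single
#' capillary-lumen (endocapillary) region. With no detected regions both
#' flags are `FALSE`.
#'
#' @param nuclei_centroids n x 2 matrix of nucleus centroids (40x space).
#' @param mesangial_regions,endocap_regions lists of region
#'   [wsi_instance()]s (40x space).
#' @return list with logical `mesangial`, `endocap` and the per-region counts.
#' @export
hypercellularity_flags <- function(nuclei_centroids, mesangial_regions = list(),
                                   endocap_regions = list()) {
  nuclei_centroids <- matrix(as.numeric(nuclei_centroids), ncol = 2L)
  count_in <- function(region) {
    if (!nrow(nuclei_centroids)) return(0L)
    sum(point_in_polygon(nuclei_centroids[, 1L], nuclei_centroids[, 2L],
                         region$polygon))
  }
  mes_counts <- vapply(mesangial_regions, count_in, integer(1L))
  endo_counts <- vapply(endocap_regions, count_in, integer(1L))
  list(
    mesangial = any(mes_counts >= 4L),
    endocap = any(endo_counts >= 2L),
    mesangial_counts = mes_counts,
    endocap_counts = endo_counts
  )
}

#' Age bins of the cohort analyses
#'
#' The four paediatric age groups: 1-5, 6-10, 11-15 and 16-20 years.
#'
#' @return character vector of bin labels.
#' @export
age_bins <- function() c("1-5", "6-10", "11-15", "16-20")

#' @rdname age_bins
#' @param age numeric vector of ages in years (1..20).
#' @return `age_group` returns a factor over [age_bins()].
#' @export
age_group <- function(age) {
  if (any(age < 1 | age > 20)) stop("ages must lie in 1..20")
  cut(age, breaks = c(0.5, 5.5, 10.5, 15.5, 20.5), labels = age_bins())
}

#' Per-slide cohort table
#'
#' Joins per-slide aggregates (glomerulus count, mean glomerular area) to the
#' cohort metadata (age with its bin, sex, diagnosis). Every result must have
#' a metadata row.
#'
#' @param results named list of `whole_slide_result` objects (names or
#'   `slide_id` fields identify slides).
#' @param metadata data.frame with columns `slide_id`, `age`, `sex`,
#'   `diagnosis`.
#' @return data.frame, one row per slide.
#' @export
cohort_table <- function(results, metadata) {
  need <- c("slide_id", "age", "sex", "diagnosis")
  stopifnot(all(need %in% names(metadata)))
  rows <- lapply(results, function(res) {
    sid <- res$slide_id
    m <- metadata[metadata$slide_id == sid, , drop = FALSE]
    if (nrow(m) != 1L) {
      stop("missing metadata row for slide_id ", sid)
    }
    labs <- vapply(res$structures, `[[`, "", "label")
    gl <- res$structures[labs %in% glomerulus_labels()]
    areas <- vapply(gl, function(g) poly_area(g$polygon), 0) * mpp_for("10x")^2
    data.frame(
      slide_id = sid,
      n_glomeruli = length(gl),
      mean_glom_area_um2 = if (length(areas)) mean(areas) else NA_real_,
      age = m$age,
      age_group = as.character(age_group(m$age)),
      sex = m$sex,
      diagnosis = m$diagnosis,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
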