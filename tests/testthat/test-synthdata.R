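test_that("config validation names the offending field", {
  expect_error(synth_config(n_glomeruli = -1), "n_glomeruli")
  expect_error(synth_config(crescent_fraction = 1.2), "crescent_fraction")
  expect_error(
    synth_config(slide_width_10x = 100, slide_height_10x = 100),
    "slide_width_10x"
  )
  expect_error(synth_config(glomerulus_radius_range_10x = c(60, 30)),
               "glomerulus_radius_range_10x")
})

test_that("generation is deterministic: same config, identical output", {
  cfg <- small_config(seed = 77L, n_glomeruli = 3L, n_proximal = 2L,
                      n_distal = 2L, n_arteries = 1L)
  a <- generate_slide_pair(cfg, render = "he10")
  b <- generate_slide_pair(cfg, render = "he10")
  expect_identical(a$he10$pixels, b$he10$pixels)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("planted counts, scale relation and containment hold", {
  cfg <- small_config(seed = 12L, n_glomeruli = 12L, crescent_fraction = 0,
                      width = 1024L)
  sp <- generate_slide_pair(cfg, render = "he10")
  gt <- sp$ground_truth
  tab <- gt_label_table(gt)
  expect_equal(unname(tab[["glomerulus_no_crescent"]]), 12L)
  expect_equal(unname(tab[["glomerular_tuft"]]), 12L)
  expect_false("glomerulus_crescent" %in% names(tab))

  # 40x rasters have exactly 4x the linear dimensions of the 10x raster
  sp2 <- shared_pair()
  expect_equal(dim(sp2$he40$pixels)[1:2], 4L * dim(sp2$he10$pixels)[1:2])
  expect_equal(dim(sp2$pas40$pixels)[1:2], 4L * dim(sp2$he10$pixels)[1:2])

  # bbox at 40x equals exactly 4x the bbox at 10x for every structure
  for (inst in gt$structures) {
    inst40 <- gt_instances(gt, "40x", labels = inst$label)
    # locate the matching instance by scaled bbox
    hit <- Filter(function(j) all(j$bbox == 4 * inst$bbox), inst40)
    expect_gte(length(hit), 1L)
  }

  # tuft strictly inside its glomerulus; crescent inside glomerulus \ tuft
  pg <- gt$per_glomerulus
  labs <- vapply(gt$structures, `[[`, "", "label")
  gl <- gt$structures[labs %in% c("glomerulus_crescent", "glomerulus_no_crescent")]
  tf <- gt$structures[labs == "glomerular_tuft"]
  for (i in seq_along(gl)) {
    expect_true(all(point_in_polygon(tf[[i]]$polygon[, 1], tf[[i]]$polygon[, 2],
                                     gl[[i]]$polygon)))
  }
})

test_that("nuclei centroids lie inside their assigned tuft and regions", {
  sp <- shared_pair()
  gt <- sp$ground_truth
  labs <- vapply(gt$structures, `[[`, "", "label")
  tufts40 <- lapply(gt$structures[labs == "glomerular_tuft"],
                    function(t) t$polygon * 4)
  for (nuc in gt$nuclei) {
    ctr <- poly_centroid(nuc$polygon)
    inside_any <- any(vapply(tufts40, function(tp) {
      point_in_polygon(ctr[1], ctr[2], tp)
    }, logical(1)))
    expect_true(inside_any)
  }
  # hypercellular regions planted with enough nuclei for their flags
  pg <- gt$per_glomerulus
  expect_true(all(pg$n_nuclei_mesangial[pg$mesangial_hyper] >= 4))
  expect_true(all(pg$n_nuclei_endocap[pg$endocap_hyper] >= 2))
})

test_that("cohort generation reproduces and recovers planted age-area ordering", {
  base <- synth_config(
    seed = 99L, slide_width_10x = 704L, slide_height_10x = 704L,
    n_glomeruli = 4L, n_proximal = 2L, n_distal = 2L, n_arteries = 1L,
    crescent_fraction = 0, mesangial_hyper_fraction = 0,
    endocap_hyper_fraction = 0, glomerulus_radius_range_10x = c(24L, 40L)
  )
  spec <- cohort_metadata_spec(
    age_sampler = function(n) rep(c(3L, 8L, 13L, 18L), length.out = n)
  )
  co <- generate_cohort(base, 12L, spec)
  expect_equal(nrow(co$metadata), 12L)
  co2 <- generate_cohort(base, 12L, spec)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$planted, co2$planted)

  # planted mean areas strictly increase across age groups (oracle: recompute
  # directly from the planted polygons, which is what co$planted holds)
  by_group <- tapply(co$planted$mean_glom_area_um2,
                     co$metadata$age_group, mean)[age_bins()]
  expect_true(all(diff(by_group) > 0))

  # null case: equal radii across groups give no systematic ordering
  spec0 <- cohort_metadata_spec(
    radius_scale_by_age = c("1-5" = 1, "6-10" = 1, "11-15" = 1, "16-20" = 1),
    age_sampler = function(n) rep(c(3L, 8L, 13L, 18L), length.out = n)
  )
  co0 <- generate_cohort(base, 8L, spec0)
  rng <- range(co0$planted$mean_glom_area_um2)
  # same sampling distribution in every group: spread stays well inside the
  # scaled cohort's 1.6^2 fold change
  expect_lt(rng[2] / rng[1], 1.6^2)
})

test_that("every label in the annotation scheme is plantable", {
  cfg <- small_config(seed = 5L, width = 768L, n_glomeruli = 4L,
                      crescent_fraction = 0.5,
                      mesangial_hyper_fraction = 0.5,
                      endocap_hyper_fraction = 0.5)
  sp <- generate_slide_pair(cfg, render = character(0))
  gt <- sp$ground_truth
  planted <- unique(c(
    vapply(gt$structures, `[[`, "", "label"),
    vapply(gt$nuclei, `[[`, "", "label"),
    vapply(gt$regions, `[[`, "", "label")
  ))
  expect_setequal(planted, wsi_labels())
})
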