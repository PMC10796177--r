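test_that("iou arithmetic and input validation", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 2, 2)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 2, 2)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "positive")
})

test_that("nms matches the O(n^2) brute-force oracle on random instances", {
  set.seed(61)
  for (rep in 1:8) {
    n <- sample(c(20, 50, 200), 1)
    insts <- random_boxes(n, extent = 150, wmax = 70)
    kept <- nms(insts)
    oracle <- insts[nms_oracle(insts)]
    expect_equal(lapply(kept, `[[`, "bbox"), lapply(oracle, `[[`, "bbox"))
    # idempotence
    expect_equal(length(nms(kept)), length(kept))
  }
  # trivial cases
  two <- list(box_instance(0, 0, 10, 10, score = 0.9),
              box_instance(0, 0, 10, 10, score = 0.8))
  expect_equal(length(nms(two)), 1L)
  expect_equal(nms(two)[[1]]$score, 0.9)
  disj <- list(box_instance(0, 0, 10, 10, score = 0.9),
               box_instance(50, 50, 10, 10, score = 0.8))
  expect_equal(length(nms(disj)), 2L)
  expect_error(nms(list(box_instance(0, 0, 1, 1))), "score")
})

test_that("rescaling is exact arithmetic and self-inverse", {
  b <- box_instance(100, 200, 40, 40, score = 0.5)
  down <- rescale_instances(list(b), 1 / 4)[[1]]
  expect_equal(unname(down$bbox), c(25, 50, 10, 10))
  up <- rescale_instances(list(down), 4, magnification = "10x")[[1]]
  expect_equal(up$polygon, b$polygon)
  expect_equal(poly_area(rescale_instances(list(b), 4)[[1]]$polygon),
               16 * poly_area(b$polygon))
  # PAS transfer is x4 on (x, y, w, h)
  tr <- transfer_to_pas(list(box_instance(10, 20, 30, 40, score = 1)))[[1]]
  expect_equal(unname(tr$bbox), c(40, 80, 120, 160))
  expect_equal(tr$magnification, "40x")
})

test_that("duplicate detections across overlapping tiles fuse to one instance", {
  # the same object detected in two tiles whose windows overlap by n/2
  tfA <- patch_transform(0, 0, 700, 768 / 700)
  tfB <- patch_transform(350, 0, 700, 768 / 700)
  obj <- function(x0) {
    poly <- rbind(c(400, 100), c(460, 100), c(460, 160), c(400, 160))
    local <- poly
    local[, 1] <- (local[, 1] - x0) * 768 / 700
    local[, 2] <- local[, 2] * 768 / 700
    wsi_instance("glomerulus_no_crescent", local, score = 1)
  }
  res <- assemble_slide(
    list(list(instances = list(obj(0)), transform = tfA),
         list(instances = list(obj(350)), transform = tfB)),
    slide_id = "s"
  )
  expect_equal(length(res$structures), 1L)
  expect_equal(unname(res$structures[[1]]$bbox), c(400, 100, 60, 60),
               tolerance = 1e-9)
})

test_that("per-class NMS never suppresses nested instances of another class", {
  tf <- patch_transform(0, 0, 700, 1)
  glom <- box_instance(100, 100, 80, 80, score = 1)
  tuft <- box_instance(110, 110, 60, 60, label = "glomerular_tuft", score = 1)
  res <- assemble_slide(list(list(instances = list(glom, tuft), transform = tf)),
                        slide_id = "s")
  expect_equal(length(res$structures), 2L)
})

test_that("nuclei integrate at 1/4 scale with tuft-first centroid assignment", {
  tf10 <- patch_transform(0, 0, 700, 1)
  tf40 <- patch_transform(0, 0, 2800, 1)
  glom <- box_instance(100, 100, 80, 80, score = 1)
  tuft <- box_instance(110, 110, 60, 60, label = "glomerular_tuft", score = 1)
  # nucleus at 40x planted at the tuft centre (10x centre 140 -> 40x 560)
  nuc <- box_instance(556, 556, 8, 8, label = "nucleus", score = 1,
                      magnification = "40x")
  # a second nucleus outside every structure
  out <- box_instance(2000, 2000, 8, 8, label = "nucleus", score = 1,
                      magnification = "40x")
  res <- assemble_slide(
    list(list(instances = list(glom, tuft), transform = tf10)),
    list(list(instances = list(nuc, out), transform = tf40)),
    slide_id = "s"
  )
  expect_equal(length(res$nuclei_10x), 2L)
  expect_equal(res$assignment$structure_label,
               c("glomerular_tuft", "interstitial"))
  # rescale is exactly 1/4
  expect_equal(res$nuclei_10x[[1]]$bbox, nuc$bbox / 4, ignore_attr = TRUE)
})

test_that("transferred PAS boxes contain the planted 40x polygons", {
  sp <- shared_pair()
  gt <- sp$ground_truth
  labs <- vapply(gt$structures, `[[`, "", "label")
  gl <- gt$structures[labs %in% c("glomerulus_crescent", "glomerulus_no_crescent")]
  boxes40 <- transfer_to_pas(lapply(gl, function(g) {
    wsi_instance(g$label, g$polygon, score = 1, magnification = "10x")
  }))
  for (i in seq_along(gl)) {
    p40 <- gl[[i]]$polygon * 4
    bb <- boxes40[[i]]$bbox
    expect_true(all(p40[, 1] >= bb[1] & p40[, 1] <= bb[1] + bb[3] &
                    p40[, 2] >= bb[2] & p40[, 2] <= bb[2] + bb[4]))
  }
})
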