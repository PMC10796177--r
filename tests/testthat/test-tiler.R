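test_that("tile_config enforces the stride = n/2 contract", {
  expect_equal(tile_config_for("10x")$n, 700L)
  expect_equal(tile_config_for("10x")$target_size, 768L)
  expect_equal(tile_config_for("40x")$n, 2800L)
  expect_equal(tile_config_for("40x")$target_size, 1024L)
  expect_equal(tile_config_for("10x")$stride, 350L)
  expect_error(tile_config(700, 768, stride = 300), "stride")
  expect_error(tile_config(701, 768), "even")
})

test_that("otsu threshold matches the exhaustive between-class variance oracle", {
  otsu_oracle <- function(vals) {
    counts <- tabulate(vals + 1L, nbins = 256L)
    total <- sum(counts)
    best_var <- -Inf; best_t <- integer(0)
    for (t in 0:255) {
      w0 <- sum(counts[seq_len(t + 1L)]) / total
      w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- sum(counts[seq_len(t + 1L)] * 0:t) / sum(counts[seq_len(t + 1L)])
      mu1 <- sum(counts[(t + 2L):256L] * (t + 1L):255L) / sum(counts[(t + 2L):256L])
      v <- w0 * w1 * (mu0 - mu1)^2
      if (v > best_var + 1e-12) { best_var <- v; best_t <- t }
      else if (abs(v - best_var) <= 1e-12) best_t <- c(best_t, t)
    }
    mean(range(best_t)) + 0.5
  }
  set.seed(21)
  for (rep in 1:5) {
    vals <- c(
      pmin(255L, pmax(0L, round(rnorm(4000, 80, sd = sample(5:20, 1))))),
      pmin(255L, pmax(0L, round(rnorm(6000, 250, sd = 3))))
    )
    t_pkg <- otsu_threshold(vals)
    t_orc <- otsu_oracle(as.integer(vals))
    expect_equal(t_pkg, t_orc)
    expect_gt(t_pkg, 80); expect_lt(t_pkg, 250)
  }
})

test_that("degenerate and bimodal foreground masks behave per contract", {
  flat <- slide_image(array(255L, dim = c(32, 32, 3)), "HE", "10x", "flat")
  expect_false(any(foreground_mask(flat)))

  sp <- shared_pair()
  fg <- foreground_mask(sp$he10)
  # foreground must cover every planted instance mask
  for (inst in sp$ground_truth$structures) {
    m <- rasterize_polygon(inst$polygon, ncol(fg), nrow(fg))
    expect_true(all(fg[m]))
  }
})

test_that("plan_tiles puts origins on the clamped lattice and keeps coverage", {
  cfg <- tile_config(700, 768)
  all_fg <- matrix(TRUE, 1400, 1400)
  plan <- plan_tiles(all_fg, cfg)
  expect_setequal(unique(plan$x0), c(0, 350, 700))
  expect_setequal(unique(plan$y0), c(0, 350, 700))

  expect_equal(nrow(plan_tiles(matrix(FALSE, 1400, 1400), cfg)), 0L)

  # slide smaller than n: single origin (0, 0)
  small <- plan_tiles(matrix(TRUE, 512, 512), cfg)
  expect_equal(nrow(small), 1L)
  expect_equal(c(small$x0, small$y0), c(0, 0))

  # property: any foreground object with diameter <= stride is fully inside
  # at least one kept tile (brute-force containment over the plan)
  set.seed(31)
  for (rep in 1:10) {
    W <- sample(800:1600, 1); H <- sample(800:1600, 1)
    mask <- matrix(FALSE, H, W)
    d <- sample(20:350, 1)
    x <- sample(0:(W - d), 1); y <- sample(0:(H - d), 1)
    mask[(y + 1):(y + d), (x + 1):(x + d)] <- TRUE
    plan <- plan_tiles(mask, cfg)
    contained <- any(plan$x0 <= x & x + d <= plan$x0 + cfg$n &
                     plan$y0 <= y & y + d <= plan$y0 + cfg$n)
    expect_true(contained)
  }
})

test_that("extract_patch pads, rescales and records the exact transform", {
  set.seed(41)
  px <- array(sample(0:255, 1050 * 1050 * 3, replace = TRUE), dim = c(1050, 1050, 3))
  slide <- slide_image(px, "HE", "10x", "s")
  cfg <- tile_config(700, 768)
  ex <- extract_patch(slide, c(350, 0), cfg)
  expect_equal(dim(ex$patch), c(768L, 768L, 3L))
  expect_equal(ex$transform$scale, 768 / 700)
  expect_error(extract_patch(slide, c(123, 0), cfg), "lattice")

  # constant crop stays constant through pad + resize
  flat <- slide_image(array(99L, dim = c(700, 700, 3)), "HE", "10x", "f")
  exf <- extract_patch(flat, c(0, 0), cfg)
  expect_equal(range(exf$patch), c(99L, 99L))

  cfg40 <- tile_config_for("40x")
  expect_equal(cfg40$target_size / cfg40$n, 1024 / 2800)
})

test_that("patch -> slide coordinate mapping inverts exactly", {
  tf <- patch_transform(x0 = 350, y0 = 0, n = 700, scale = 768 / 700)
  inst <- box_instance(0, 0, 768, 768, score = 0.9)
  back <- to_slide_coords(inst, tf)
  expect_equal(unname(back$bbox), c(350, 0, 700, 700))

  ident <- patch_transform(0, 0, 700, 1)
  expect_equal(to_slide_coords(inst, ident)$polygon, inst$polygon)

  # round trip slide -> patch -> slide over random boxes
  set.seed(51)
  worst <- 0
  for (i in 1:100) {
    tf <- patch_transform(x0 = sample(0:2000, 1) , y0 = sample(0:2000, 1),
                          n = 700, scale = sample(c(768 / 700, 1024 / 2800), 1))
    b <- random_boxes(1, extent = 600)[[1]]
    fwd <- b$polygon
    fwd[, 1] <- (fwd[, 1] - tf$x0 + tf$pad_left) * tf$scale
    fwd[, 2] <- (fwd[, 2] - tf$y0 + tf$pad_top) * tf$scale
    patch_inst <- wsi_instance(b$label, fwd, score = b$score)
    back <- to_slide_coords(patch_inst, tf)
    worst <- max(worst, max(abs(back$polygon - b$polygon)))
  }
  expect_lt(worst, 0.5)
})
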