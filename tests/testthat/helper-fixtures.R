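# shared fixture builders: everything is generated in code at test time

# axis-aligned box instance (x, y, w, h) as a rectangle polygon
box_instance <- function(x, y, w, h, label = "glomerulus_no_crescent",
                         score = NULL, magnification = "10x") {
  poly <- rbind(c(x, y), c(x + w, y), c(x + w, y + h), c(x, y + h))
  wsi_instance(label, poly, score = score, magnification = magnification)
}

# n random scored boxes inside [0, extent)^2
random_boxes <- function(n, extent = 200, wmax = 60,
                         label = "glomerulus_no_crescent", scored = TRUE) {
  lapply(seq_len(n), function(i) {
    w <- runif(1, 5, wmax); h <- runif(1, 5, wmax)
    x <- runif(1, 0, extent - w); y <- runif(1, 0, extent - h)
    box_instance(x, y, w, h, label = label,
                 score = if (scored) runif(1, 0.05, 1) else NULL)
  })
}

# small, quick-to-render slide configuration
small_config <- function(seed, width = 700L, height = width,
                         n_glomeruli = 5L, crescent_fraction = 0.4,
                         n_proximal = 4L, n_distal = 3L, n_arteries = 2L, ...) {
  synth_config(
    seed = seed, slide_width_10x = width, slide_height_10x = height,
    n_glomeruli = n_glomeruli, crescent_fraction = crescent_fraction,
    n_proximal = n_proximal, n_distal = n_distal, n_arteries = n_arteries,
    glomerulus_radius_range_10x = c(26L, 48L), ...
  )
}

gt_label_table <- function(gt) {
  table(vapply(gt$structures, `[[`, "", "label"))
}

# one small fully rendered slide pair, cached across tests in a session
shared_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_slide_pair(small_config(seed = 42L))
    }
    cache
  }
})
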