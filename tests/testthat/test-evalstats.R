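# oracles live in helper-oracles.R (shared with the acceptance suite)

test_that("match_detections equals the brute-force greedy oracle", {
  set.seed(71)
  for (rep in 1:10) {
    gts <- random_boxes(10, extent = 120, scored = FALSE)
    dets <- random_boxes(30, extent = 120)
    m <- match_detections(dets, gts)
    o <- match_oracle(dets, gts)
    expect_identical(m$tp, o$tp)
    expect_identical(m$gt_matched, o$matched)
    expect_equal(sum(m$tp) + sum(!m$tp), 30L)
    expect_lte(sum(m$tp), 10L)
  }
  # double detection of one GT: higher score TP, lower FP
  gt <- list(box_instance(0, 0, 20, 20))
  dd <- list(box_instance(0, 0, 20, 20, score = 0.9),
             box_instance(1, 0, 20, 20, score = 0.7))
  mm <- match_detections(dd, gt)
  expect_identical(mm$tp, c(TRUE, FALSE))
  expect_error(
    match_detections(list(box_instance(0, 0, 1, 1, label = "artery", score = 1)),
                     gt),
    "single class"
  )
})

test_that("11-point AP agrees with the literal interpolation oracle", {
  set.seed(81)
  for (rep in 1:20) {
    n_gt <- sample(1:20, 1)
    gts <- random_boxes(n_gt, extent = 100, scored = FALSE)
    dets <- random_boxes(sample(1:40, 1), extent = 100)
    m <- match_detections(dets, gts)
    expect_equal(average_precision_11pt(m), ap_oracle(m$tp, n_gt))
  }
  # perfect detector -> AP 1; no detections -> AP 0
  gts <- random_boxes(5, extent = 100, scored = FALSE)
  perfect <- lapply(gts, function(g) {
    wsi_instance(g$label, g$polygon, score = 0.9)
  })
  expect_equal(average_precision_11pt(match_detections(perfect, gts)), 1.0)
  expect_equal(average_precision_11pt(match_detections(list(), gts)), 0.0)
  expect_error(average_precision_11pt(match_detections(list(), list())),
               "zero ground truths")
  # adding a zero-IoU lowest-score detection never increases AP
  set.seed(82)
  for (rep in 1:5) {
    gts <- random_boxes(6, extent = 80, scored = FALSE)
    dets <- random_boxes(10, extent = 80)
    ap1 <- average_precision_11pt(match_detections(dets, gts))
    junk <- box_instance(500, 500, 5, 5, score = 0.01)
    ap2 <- average_precision_11pt(match_detections(c(dets, list(junk)), gts))
    expect_lte(ap2, ap1 + 1e-12)
  }
})

test_that("mAP is the unweighted mean of class APs", {
  expect_equal(map_over_classes(1.0), 1.0)
  expect_equal(map_over_classes(c(0.8, 0.6)), 0.7)
  set.seed(83)
  aps <- runif(5)
  expect_equal(map_over_classes(aps), sum(aps) / 5)
  expect_error(map_over_classes(numeric(0)), "at least one")
})

test_that("confusion metrics handle zero denominators as undefined", {
  expect_equal(unname(confusion_metrics(10, 10, 0, 0)), c(1, 1, 1))
  m <- confusion_metrics(8, 0, 2, 2)
  expect_equal(unname(m[c("sensitivity", "precision")]), c(0.8, 0.8))
  m0 <- confusion_metrics(0, 5, 0, 0)
  expect_true(is.na(m0["sensitivity"]))
  expect_equal(unname(m0["specificity"]), 1)
})

test_that("AUC equals the exhaustive pairwise oracle and is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(91)
  for (rep in 1:10) {
    n <- 40
    scores <- round(runif(n), 2)  # induce ties
    labels <- runif(n) > 0.5
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_oracle(scores, labels))
    # invariance under strictly monotone transform
    expect_equal(roc_auc(exp(3 * scores), labels)$auc, r$auc)
  }
})

test_that("spearman equals rank-then-Pearson with t-approximation p", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(spearman(x, sqrt(x))$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  expect_true(is.na(spearman(rep(1, 5), 1:5)$rho))
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    x <- sample(1:10, n, replace = TRUE)  # ties
    y <- sample(1:10, n, replace = TRUE)
    s <- spearman(x, y)
    rho_oracle <- stats::cor(rank(x), rank(y))
    expect_equal(s$rho, rho_oracle)
    if (abs(rho_oracle) < 1) {
      tstat <- rho_oracle * sqrt((n - 2) / (1 - rho_oracle^2))
      expect_equal(s$p_value, 2 * pt(-abs(tstat), n - 2))
    }
  }
})

test_that("ICC(A,1) matches the first-principles sums-of-squares oracle", {
  set.seed(111)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    x <- cbind(rnorm(n), rnorm(n), if (runif(1) > 0.5) rnorm(n))
    r <- icc_absolute_single(x)
    expect_equal(r$icc, icc_oracle(x), tolerance = 1e-10)
    expect_lte(r$ci[1], r$icc + 1e-8)
    expect_gte(r$ci[2], r$icc - 1e-8)
    # invariance under adding a common constant
    expect_equal(icc_absolute_single(x + 100)$icc, r$icc, tolerance = 1e-8)
  }
  # duplicated rater -> ICC = 1
  subj <- rnorm(10, sd = 3)
  expect_equal(icc_absolute_single(cbind(subj, subj))$icc, 1)
  # absolute agreement penalises a constant offset vs consistency ICC
  shifted <- cbind(subj, subj + 5)
  icc_a <- icc_absolute_single(shifted)$icc
  # consistency-type ICC on the same data from its mean squares
  n <- 10; k <- 2
  gm <- mean(shifted)
  msr <- k * sum((rowMeans(shifted) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(shifted) - gm)^2) / (k - 1)
  mse <- (sum((shifted - gm)^2) - (n - 1) * msr - (k - 1) * msc / 1) /
    ((n - 1) * (k - 1))
  mse <- max(mse, 0)
  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  expect_lt(icc_a, icc_c)
  expect_error(icc_absolute_single(cbind(c(1, NA, 3), 1:3)), "complete")
})

test_that("one-way ANOVA + Tukey match stats::aov / TukeyHSD and closed forms", {
  set.seed(121)
  # two groups: F equals t^2 from the pooled t-test
  a <- rnorm(12); b <- rnorm(15, mean = 1)
  res <- anova_tukey(c(a, b), rep(c("A", "B"), c(12, 15)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)

  # random 4-group data: SS decomposition against from-scratch oracle and
  # Tukey against stats::TukeyHSD (unbalanced -> Tukey-Kramer)
  for (rep in 1:5) {
    ns <- sample(4:9, 4, replace = TRUE)
    g <- rep(letters[1:4], ns)
    y <- rnorm(sum(ns)) + rep(rnorm(4, sd = 1.5), ns)
    res <- anova_tukey(y, g)
    fit <- stats::aov(y ~ g2, data = data.frame(y = y, g2 = factor(g)))
    ref <- summary(fit)[[1]]
    expect_equal(res$F, ref[["F value"]][1], tolerance = 1e-9)
    expect_equal(res$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-9)
    thsd <- stats::TukeyHSD(fit)$g2
    ours <- res$tukey[match(rownames(thsd), res$tukey$comparison), ]
    expect_equal(ours$diff, unname(thsd[, "diff"]), tolerance = 1e-9)
    expect_equal(ours$p_adj, unname(thsd[, "p adj"]), tolerance = 1e-7)
    expect_equal(ours$lwr, unname(thsd[, "lwr"]), tolerance = 1e-7)
  }
  # identical groups -> F = 0, p = 1; F invariant under common shift
  same <- rep(c(3, 4, 5), 3)
  res0 <- anova_tukey(same, rep(c("a", "b", "c"), each = 3))
  expect_equal(res0$F, 0)
  expect_equal(res0$p_value, 1)
  y <- rnorm(20); g <- rep(c("a", "b"), 10)
  expect_equal(anova_tukey(y + 50, g)$F, anova_tukey(y, g)$F, tolerance = 1e-9)
  expect_error(anova_tukey(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("review triage selects the lowest-mAP fraction with tie expansion", {
  maps <- c(img1 = 0.9, img2 = 0.1, img3 = 0.5, img4 = 0.05, img5 = 0.8,
            img6 = 0.7, img7 = 0.6, img8 = 0.95, img9 = 0.4, img10 = 0.3)
  expect_setequal(review_triage(maps, 0.2), c("img4", "img2"))
  all_equal <- rep(0.5, 6)
  expect_equal(length(review_triage(all_equal, 0.2)), 6L)
  expect_error(review_triage(maps, 0), "fraction")
  set.seed(131)
  for (rep in 1:5) {
    m <- round(runif(100), 1)  # heavy ties
    sel <- review_triage(m, 0.2)
    k <- ceiling(0.2 * 100)
    cutoff <- sort(m)[k]
    expect_setequal(sel, which(m <= cutoff))
    expect_gte(length(sel), k)
  }
})
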