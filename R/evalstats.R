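#' Greedy score-ordered detection matching
#'
#' VOC-style matching at a fixed IoU threshold: detections are processed in
#' descending score order; each is matched to the not-yet-matched ground
#' truth with the highest IoU if that IoU reaches the threshold (TP),
#' otherwise it is a false positive. Each ground truth can be matched at most
#' once (duplicate detections of one object are FPs); unmatched ground truths
#' are the false negatives.
#'
#' @param detections list of scored [wsi_instance()] of one class.
#' @param ground_truth list of [wsi_instance()] of the same class.
#' @param iou_threshold matching threshold (default 0.5, i.e. AP50).
#' @return object of class `match_result`: `tp` logical per detection (score
#'   order), `scores`, `gt_matched` logical per GT, `n_gt`, `order` (index of
#'   each processed detection in the input list), `iou_threshold`.
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  all_labs <- c(
    vapply(detections, `[[`, "", "label"),
    vapply(ground_truth, `[[`, "", "label")
  )
  if (length(unique(all_labs)) > 1L) {
    stop("match_detections expects a single class; got: ",
         paste(unique(all_labs), collapse = ", "))
  }
  scores <- vapply(detections, `[[`, 0, "score")
  ord <- order(-scores, seq_along(detections))
  G <- instance_boxes(ground_truth)
  gt_matched <- rep(FALSE, length(ground_truth))
  tp <- logical(length(detections))
  for (k in seq_along(ord)) {
    d <- detections[[ord[k]]]
    if (!nrow(G)) next
    ious <- iou_many(d$bbox, G)
    ious[gt_matched] <- -1
    best <- which.max(ious)
    if (length(best) && ious[best] >= iou_threshold) {
      gt_matched[best] <- TRUE
      tp[k] <- TRUE
    }
  }
  structure(
    list(
      tp = tp, scores = scores[ord], gt_matched = gt_matched,
      n_gt = length(ground_truth), order = ord, iou_threshold = iou_threshold
    ),
    class = "match_result"
  )
}

#' 11-point interpolated average precision
#'
#' PASCAL VOC 2010 11-point AP: with detections in descending score order,
#' compute precision p(r~) and recall r~ at every rank; the interpolated
#' precision at recall r is the maximum p(r~) over all r~ >= r (0 if no rank
#' attains recall r), and AP is the mean of the interpolated precision over
#' r in {0, 0.1, ..., 1}. The interpolation makes the precision-recall curve
#' monotone non-increasing.
#'
#' @param match a `match_result` with at least one ground truth.
#' @return AP in [0, 1].
#' @export
average_precision_11pt <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (match$n_gt < 1L) stop("average precision is undefined with zero ground truths")
  if (!length(match$tp)) return(0)
  ctp <- cumsum(match$tp)
  cfp <- cumsum(!match$tp)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / match$n_gt
  r_levels <- seq(0, 1, by = 0.1)
  p_interp <- vapply(r_levels, function(r) {
    ok <- rec >= r
    if (!any(ok)) 0 else max(prec[ok])
  }, 0)
  mean(p_interp)
}

#' Mean average precision over classes
#'
#' @param aps numeric vector of per-class APs (>= 1 class).
#' @return unweighted arithmetic mean.
#' @export
map_over_classes <- function(aps) {
  if (!length(aps)) stop("mAP requires at least one class AP")
  mean(aps)
}

#' Confusion-count metrics
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)` and precision
#' `TP/(TP+FP)`. A metric with a zero denominator is undefined and reported
#' as `NA` (never as 0). True negatives are not defined for detection tasks;
#' specificity is meaningful only for patch- or classification-level counts.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return named numeric vector `c(sensitivity, specificity, precision)`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    precision = safe(tp, tp + fp)
  )
}

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney probability
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from ranks; the curve is
#' swept over descending score thresholds.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return list with `points` (data.frame fpr/tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) {
    stop("roc_auc requires both classes to be present")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(-scores)
  tpr <- c(0, cumsum(labels[ord]) / npos)
  fpr <- c(0, cumsum(!labels[ord]) / nneg)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mean ranks (ties get the average rank); the
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom.
#' A constant vector makes the coefficient undefined (`NA`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Two-way absolute-agreement single-measurement ICC with 95% CI
#'
#' ICC(A,1) in the McGraw-Wong nomenclature (two-way model, absolute
#' agreement, reliability of a single measurement): from the two-way ANOVA
#' mean squares for rows/subjects (MSR), columns/raters (MSC) and error
#' (MSE),
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% confidence interval uses the F-based interval with Satterthwaite
#' degrees of freedom.
#'
#' @param ratings complete n x k matrix (n subjects >= 3, k raters >= 2).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci` (low, high), `model`.
#' @export
icc_absolute_single <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings table must be complete (no missing cells)")
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 3L, k >= 2L)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # degenerate perfect agreement
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(icc, icc)
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
      ci <- c(lo, hi)
    }
  }
  structure(
    list(icc = icc, ci = ci,
         model = "two-way, absolute agreement, single measurement (ICC(A,1))"),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f (95%% CI %.4f-%.4f)\n%s\n",
              x$icc, x$ci[1L], x$ci[2L], x$model))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' One-way F test across groups followed by all pairwise Tukey HSD
#' comparisons on the studentized-range distribution, with the Tukey-Kramer
#' standard error for unequal group sizes. Two-sided; significance threshold
#' alpha = 0.05 by convention.
#'
#' @param values numeric observations.
#' @param groups factor/character of group membership (>= 2 groups, each
#'   n >= 2).
#' @return list with `F`, `p_value`, `df` and `tukey` (data.frame of pairwise
#'   differences with adjusted p-values and 95% family-wise intervals).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  if (length(lv) < 2L) stop("ANOVA requires at least two groups")
  ns <- table(groups)
  if (any(ns < 2L)) stop("each group must have n >= 2")
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- length(lv) - 1L
  df2 <- n - length(lv)
  ms_between <- ss_between / df1
  ms_within <- ss_within / df2
  f <- if (ms_within == 0) {
    if (ms_between == 0) 0 else Inf
  } else ms_between / ms_within
  p <- if (is.infinite(f)) 0 else 1 - stats::pf(f, df1, df2)

  pairs <- utils::combn(lv, 2L)
  tuk <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    diff <- means[[j]] - means[[i]]
    se <- sqrt(ms_within / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    qstat <- if (se == 0) if (diff == 0) 0 else Inf else abs(diff) / se
    p_adj <- if (is.infinite(qstat)) 0 else {
      stats::ptukey(qstat, nmeans = length(lv), df = df2, lower.tail = FALSE)
    }
    qcrit <- stats::qtukey(0.95, nmeans = length(lv), df = df2)
    c(diff = diff, lwr = diff - qcrit * se, upr = diff + qcrit * se,
      p_adj = p_adj)
  })
  tukey <- data.frame(
    comparison = paste(pairs[2L, ], pairs[1L, ], sep = "-"),
    t(tuk), stringsAsFactors = FALSE
  )
  list(F = f, p_value = p, df = c(df1, df2), tukey = tukey)
}

#' Annotation-review triage by lowest mAP
#'
#' Returns the images whose per-image mAP falls in the lowest `fraction`
#' (ceiling of `fraction * N` images); ties at the cut are all included, so
#' the selection may exceed that count.
#'
#' @param maps named numeric vector of per-image mAPs.
#' @param fraction fraction in (0, 1] (default 0.2, the lowest 20%).
#' @return names (or indices if unnamed) of the selected images.
#' @export
review_triage <- function(maps, fraction = 0.2) {
  if (!length(maps)) stop("review_triage requires at least one image")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  k <- ceiling(fraction * length(maps))
  cutoff <- sort(maps)[k]
  sel <- which(maps <= cutoff)
  if (is.null(names(maps))) sel else names(maps)[sel]
}

#' Per-class AP50 report for a detection set
#'
#' Convenience wrapper: matches detections to ground truth class by class at
#' the IoU threshold and reports per-class AP plus their mean (mAP) over the
#' classes present in the ground truth.
#'
#' @param detections,ground_truth lists of [wsi_instance()] (mixed classes).
#' @param iou_threshold matching threshold.
#' @return list with `per_class` (named APs) and `map`.
#' @export
evaluate_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  gl <- vapply(ground_truth, `[[`, "", "label")
  dl <- vapply(detections, `[[`, "", "label")
  classes <- sort(unique(gl))
  aps <- vapply(classes, function(cl) {
    m <- match_detections(detections[dl == cl], ground_truth[gl == cl],
                          iou_threshold)
    average_precision_11pt(m)
  }, 0)
  list(per_class = aps, map = map_over_classes(aps))
}
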