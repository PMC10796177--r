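# independent brute-force / first-principles oracles used by the module
# tests and by the acceptance criteria; these never call the code paths
# they check

nms_oracle <- function(instances, thr = 0.5) {
  # repeatedly extract the max-score unsuppressed box (ties: area, order)
  scores <- vapply(instances, `[[`, 0, "score")
  areas <- vapply(instances, function(i) i$bbox[3] * i$bbox[4], 0)
  alive <- rep(TRUE, length(instances))
  kept <- integer(0)
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[order(-scores[cand], -areas[cand], cand)][1]
    kept <- c(kept, best)
    alive[best] <- FALSE
    for (j in which(alive)) {
      if (iou(instances[[best]]$bbox, instances[[j]]$bbox) > thr) {
        alive[j] <- FALSE
      }
    }
  }
  kept
}

match_oracle <- function(dets, gts, thr = 0.5) {
  scores <- vapply(dets, `[[`, 0, "score")
  ord <- order(-scores, seq_along(dets))
  matched <- rep(FALSE, length(gts))
  tp <- logical(length(dets))
  for (k in seq_along(ord)) {
    d <- dets[[ord[k]]]
    best <- 0; best_iou <- -1
    for (g in seq_along(gts)) {
      if (matched[g]) next
      v <- iou(d$bbox, gts[[g]]$bbox)
      if (v > best_iou) { best_iou <- v; best <- g }
    }
    if (best > 0 && best_iou >= thr) { matched[best] <- TRUE; tp[k] <- TRUE }
  }
  list(tp = tp, matched = matched)
}

ap_oracle <- function(tp, n_gt) {
  # literal 11-point rule: p(r~) at every rank, maximised over suffixes
  if (!length(tp)) return(0)
  p <- numeric(length(tp)); r <- numeric(length(tp))
  for (k in seq_along(tp)) {
    p[k] <- sum(tp[1:k]) / k
    r[k] <- sum(tp[1:k]) / n_gt
  }
  total <- 0
  for (rl in seq(0, 1, by = 0.1)) {
    pm <- 0
    for (k in seq_along(tp)) if (r[k] >= rl && p[k] > pm) pm <- p[k]
    total <- total + pm
  }
  total / 11
}

auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  msr <- sum((rowMeans(x) - gm)^2) * k / (n - 1)
  msc <- sum((colMeans(x) - gm)^2) * n / (k - 1)
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (x[i, j] - rowMeans(x)[i] - colMeans(x)[j] + gm)^2
  }
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

anova_ss_oracle <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = 1 - pf(F, df1, df2))
}
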