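#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney rank statistic: the proportion of
#' (cancer, healthy) score pairs in which the cancer sample scores higher,
#' ties counted one half. The curve enumerates every observed score as a
#' threshold (prediction rule: score >= threshold is called cancer), so its
#' trapezoidal area equals the rank AUC.
#'
#' @param scores data.frame with columns \code{label} ("cancer"/"healthy")
#'   and \code{score}.
#' @return List of class \code{"fragstackRoc"}: \code{curve} (data.frame
#'   threshold / sensitivity / fpr, threshold decreasing) and \code{auc}.
#' @export
rocAuc <- function(scores) {
  ca <- scores$score[scores$label == "cancer"]
  he <- scores$score[scores$label == "healthy"]
  if (!length(ca) || !length(he))
    .stopf("both classes are required to compute a ROC curve")
  # rank formulation of the pairwise statistic (ties share ranks)
  r <- rank(c(ca, he), ties.method = "average")
  auc <- (sum(r[seq_along(ca)]) - length(ca) * (length(ca) + 1) / 2) /
    (length(ca) * length(he))
  thr <- c(Inf, sort(unique(scores$score), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(ca >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(he >= t), numeric(1)))
  structure(list(curve = curve, auc = auc), class = "fragstackRoc")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level (default 0.95).
#' @return c(lower, upper) on the proportion scale.
#' @export
clopperPearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Confusion-matrix metrics with exact confidence intervals
#'
#' Applies the fixed decision rule score >= cutoff => predicted cancer,
#' tabulates the confusion matrix, and reports sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN) and accuracy
#' (TP+TN)/total, each with an exact binomial 95\% interval. A metric with a
#' zero denominator is reported as NA with its CI omitted.
#'
#' @param scores data.frame with \code{label} and \code{score} (or
#'   \code{predicted}, used directly when \code{cutoff} is NULL).
#' @param cutoff decision threshold.
#' @param conf confidence level.
#' @return List: counts (tp, fp, tn, fn) and a data.frame \code{metrics}
#'   with estimate / lower / upper / x / n per metric.
#' @export
confusionMetrics <- function(scores, cutoff = NULL, conf = 0.95) {
  pred <- if (!is.null(cutoff)) ifelse(scores$score >= cutoff, "cancer", "healthy")
          else scores$predicted
  lab <- scores$label
  tp <- sum(pred == "cancer" & lab == "cancer")
  fp <- sum(pred == "cancer" & lab == "healthy")
  tn <- sum(pred == "healthy" & lab == "healthy")
  fn <- sum(pred == "healthy" & lab == "cancer")
  one <- function(x, n) {
    if (n == 0) return(c(est = NA_real_, lower = NA_real_, upper = NA_real_,
                         x = x, n = n))
    ci <- clopperPearson(x, n, conf)
    c(est = x / n, lower = unname(ci[1]), upper = unname(ci[2]), x = x, n = n)
  }
  m <- rbind(sensitivity = one(tp, tp + fn),
             specificity = one(tn, tn + fp),
             ppv = one(tp, tp + fp),
             npv = one(tn, tn + fn),
             accuracy = one(tp + tn, tp + fp + tn + fn))
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       metrics = as.data.frame(m))
}

#' Per-stratum sensitivity report
#'
#' Sensitivity (and its exact CI) among the true cancers of each stratum --
#' the subgroup view of detection performance by stage, histology or
#' subtype. Missing or unrecognized stratum values are grouped as
#' "Unknown"; empty strata are omitted; strata smaller than \code{minN} are
#' flagged.
#'
#' @param scores score table with \code{label}, \code{score} (cancers only
#'   are used).
#' @param strata per-sample stratum labels, aligned with \code{scores} rows.
#' @param cutoff decision threshold.
#' @param minN flag strata smaller than this (default 5).
#' @return data.frame: stratum, n, detected, sensitivity, lower, upper,
#'   small.
#' @export
stratifiedReport <- function(scores, strata, cutoff, minN = 5L) {
  strata <- as.character(strata)
  strata[is.na(strata) | !nzchar(strata)] <- "Unknown"
  ca <- scores$label == "cancer"
  sc <- scores$score[ca]
  st <- strata[ca]
  out <- lapply(sort(unique(st)), function(s) {
    i <- st == s
    n <- sum(i)
    det <- sum(sc[i] >= cutoff)
    ci <- clopperPearson(det, n)
    data.frame(stratum = s, n = n, detected = det, sensitivity = det / n,
               lower = unname(ci[1]), upper = unname(ci[2]), small = n < minN,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
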