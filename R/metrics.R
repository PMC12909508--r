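# Confusion-count metrics: specificity, accuracy, precision, recall,
# F1 and Matthews correlation coefficient, with one-vs-rest per-class
# and micro/macro aggregation for multi-class problems.

#' Metrics from confusion counts
#'
#' Computes
#' `SP = TRN/(TRN+FAP)`, `AC = (TRP+TRN)/total`, `PR = TRP/(TRP+FAP)`,
#' `RE = TRP/(TRP+FAN)`, `F1 = 2 PR RE/(PR+RE)` and
#' `MCC = (TRP*TRN - FAP*FAN) / sqrt((TRP+FAP)(TRP+FAN)(TRN+FAP)(TRN+FAN))`.
#' A zero MCC denominator factor yields `MCC = 0` by convention (logged);
#' undefined PR/RE/SP/F1 ratios yield 0.
#'
#' @param counts named numeric vector or list with `TRP`, `TRN`, `FAP`,
#'   `FAN` (true/false positives/negatives), all non-negative, total > 0.
#' @return named numeric vector with `SP`, `AC`, `PR`, `RE`, `F1`, `MCC`.
#' @export
#' @examples
#' computeMetrics(c(TRP = 50, TRN = 50, FAP = 0, FAN = 0))
computeMetrics <- function(counts) {
  tp <- counts[["TRP"]]; tn <- counts[["TRN"]]
  fp <- counts[["FAP"]]; fn <- counts[["FAN"]]
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated segments (total = 0)")
  safe <- function(num, den) if (den > 0) num / den else 0
  sp <- safe(tn, tn + fp)
  ac <- (tp + tn) / total
  pr <- safe(tp, tp + fp)
  re <- safe(tp, tp + fn)
  f1 <- safe(2 * pr * re, pr + re)
  denomFactors <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(denomFactors == 0)) {
    message("MCC denominator degenerate; reporting 0 by convention")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(prod(denomFactors))
  }
  c(SP = sp, AC = ac, PR = pr, RE = re, F1 = f1, MCC = mcc)
}

#' Confusion counts of a binary prediction
#'
#' @param predicted,truth class vectors.
#' @param positive the positive-class label.
#' @return named vector `c(TRP, TRN, FAP, FAN)`.
#' @export
confusionCounts <- function(predicted, truth, positive) {
  p <- predicted == positive
  t <- truth == positive
  c(TRP = sum(p & t), TRN = sum(!p & !t),
    FAP = sum(p & !t), FAN = sum(!p & t))
}

#' Multi-class metrics report
#'
#' One-vs-rest confusion counts and [computeMetrics()] per class, plus
#' micro (pooled counts) and macro (averaged metrics) aggregates.
#'
#' @param predicted,truth class vectors over the same label set.
#' @return list with `perClass` (data.frame), `macro`, `micro` (named
#'   vectors) and `accuracy`.
#' @export
multiclassMetrics <- function(predicted, truth) {
  classes <- sort(unique(c(as.character(predicted), as.character(truth))))
  per <- NULL
  pooled <- c(TRP = 0, TRN = 0, FAP = 0, FAN = 0)
  for (cl in classes) {
    cc <- confusionCounts(predicted, truth, cl)
    pooled <- pooled + cc
    per <- rbind(per, data.frame(class = cl, t(computeMetrics(cc))))
  }
  macro <- colMeans(per[, -1, drop = FALSE])
  micro <- suppressMessages(computeMetrics(pooled))
  list(perClass = per, macro = macro, micro = micro,
       accuracy = mean(predicted == truth))
}
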