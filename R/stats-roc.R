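#' ROC analysis with Youden-index threshold selection
#'
#' Empirical ROC curve over all cutpoints, with the AUC computed by the
#' rank (Mann-Whitney) formulation — identical to the trapezoidal area
#' under the empirical curve, with ties contributing 1/2. The optimal
#' threshold gives equal weighting to sensitivity and specificity by
#' maximizing the Youden index J = sensitivity + specificity - 1;
#' candidate thresholds are the midpoints between adjacent distinct
#' scores (ties on J resolve to the lowest such threshold). The AUC
#' confidence interval uses the DeLong variance estimator.
#'
#' @param scores numeric marker values
#' @param labels outcome labels
#' @param positive label of the positive (event) class
#' @param direction `">"` if larger scores indicate the positive class
#'   (e.g. a larger increase in AUGC indicating site failure), `"<"`
#'   otherwise
#' @param conf confidence level for the AUC interval
#' @return list of class `ROCResult`: `auc`, `ci_low`, `ci_high`,
#'   `threshold` (classify positive when `scores > threshold` for
#'   direction `">"`), `sensitivity` and `specificity` at the threshold,
#'   `direction`, and `curve` (data.frame threshold/sensitivity/
#'   specificity)
#' @examples
#' co <- generateCohort(CohortSpec(seed = 2))
#' rocAnalysis(co$pct_augc, co$outcome, positive = "SF")
#' @export
rocAnalysis <- function(scores, labels, positive = "SF",
                        direction = c(">", "<"), conf = 0.95) {
  direction <- match.arg(direction)
  stopIfNot(length(scores) == length(labels), "scores and labels must match")
  pos <- as.character(labels) == positive
  stopIfNot(any(pos) && any(!pos), "both outcome classes must be present")
  s <- if (direction == ">") scores else -scores
  sp <- s[pos]; sn <- s[!pos]
  m <- length(sp); n0 <- length(sn)

  r <- rank(c(sp, sn))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n0)

  # DeLong placement variances
  v10 <- vapply(sp, function(x) (sum(x > sn) + 0.5 * sum(x == sn)) / n0,
                numeric(1))
  v01 <- vapply(sn, function(x) (sum(sp > x) + 0.5 * sum(sp == x)) / m,
                numeric(1))
  vr <- (if (m > 1) stats::var(v10) / m else 0) +
        (if (n0 > 1) stats::var(v01) / n0 else 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(vr), 0), 1)

  su <- sort(unique(s))
  thr <- c(-Inf, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2, Inf)
  sens <- vapply(thr, function(th) mean(sp > th), numeric(1))
  spec <- vapply(thr, function(th) mean(sn <= th), numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))[1]

  orient <- function(v) if (direction == ">") v else -v
  curve <- data.frame(threshold = orient(thr), sensitivity = sens,
                      specificity = spec)
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 threshold = orient(thr[best]),
                 sensitivity = sens[best], specificity = spec[best],
                 direction = direction, curve = curve),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat("ROC: AUC ", signif(x$auc, 3), " (95% CI ", signif(x$ci_low, 3), "-",
      signif(x$ci_high, 3), "); optimal threshold ", x$direction, " ",
      signif(x$threshold, 4), " (sens ", round(100 * x$sensitivity, 1),
      "%, spec ", round(100 * x$specificity, 1), "%)\n", sep = "")
  invisible(x)
}

#' Diagnostic performance from a 2x2 confusion table
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' value, each in percent. A ratio with zero denominator is undefined and
#' reported as `NA`, never as 0.
#'
#' @param tp,fp,tn,fn confusion counts, nonnegative, positive total
#' @return one-row data.frame with the counts and the five metrics
#' @examples
#' diagnosticPerformance(tp = 10, fp = 4, tn = 15, fn = 4)
#' @export
diagnosticPerformance <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  stopIfNot(all(counts >= 0) && all(counts == round(counts)),
            "counts must be nonnegative integers")
  stopIfNot(sum(counts) > 0, "total count must be positive")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = pct(tp, tp + fn),
             specificity = pct(tn, tn + fp),
             accuracy = pct(tp + tn, sum(counts)),
             ppv = pct(tp, tp + fp),
             npv = pct(tn, tn + fn))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables (at fixed margins) no more
#' probable than the observed one.
#'
#' @param table 2x2 matrix of nonnegative counts
#' @return the two-sided p-value
#' @examples
#' fisherExact2x2(matrix(c(10, 4, 4, 15), 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(table) {
  stopIfNot(is.matrix(table) && all(dim(table) == c(2, 2)),
            "table must be a 2x2 matrix")
  stopIfNot(all(table >= 0) && sum(table) > 0,
            "counts must be nonnegative with positive total")
  stats::fisher.test(table)$p.value
}

#' Threshold a marker and tabulate diagnostic performance
#'
#' Applies a decision threshold to marker values and assembles the
#' confusion counts, diagnostic metrics and Fisher's exact p-value — the
#' layout of a diagnostic-performance table for a chosen cutoff such as a
#' percent increase in AUGC.
#'
#' @param scores marker values
#' @param labels outcome labels
#' @param threshold decision threshold
#' @param positive positive-class label
#' @param direction `">"`: call positive when `scores > threshold`
#' @return list with `table` (the [diagnosticPerformance()] row),
#'   `p_value` (Fisher) and `threshold`
#' @export
thresholdPerformance <- function(scores, labels, threshold,
                                 positive = "SF", direction = c(">", "<")) {
  direction <- match.arg(direction)
  pos <- as.character(labels) == positive
  call <- if (direction == ">") scores > threshold else scores < threshold
  tp <- sum(call & pos); fp <- sum(call & !pos)
  tn <- sum(!call & !pos); fn <- sum(!call & pos)
  perf <- diagnosticPerformance(tp, fp, tn, fn)
  p <- fisherExact2x2(matrix(c(tp, fp, fn, tn), 2, byrow = TRUE))
  list(table = perf, p_value = p, threshold = threshold)
}
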