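## Cost-sensitive operating-point selection and paired-classifier comparison.

#' Construct a misclassification cost model
#'
#' @param p,n positive / negative window counts or frequencies.
#' @param cFP,cFN unit costs of false positives / false negatives.
#' @return A [CostSpec-class].
#' @export
costSpec <- function(p, n, cFP = 1, cFN = 1)
  new("CostSpec", p = p, n = n, cFP = cFP, cFN = cFN)

#' Iso-performance line slope
#'
#' Slope of the constant-expected-cost lines in ROC space,
#' `(n / p) * (C_FP / C_FN)`.
#'
#' @param spec a [CostSpec-class].
#' @return Numeric slope.
#' @export
isoSlope <- function(spec) (spec@n / spec@p) * (spec@cFP / spec@cFN)

#' Cost-optimal ROC operating point
#'
#' The achievable point where the ROC touches the best iso-performance line:
#' the curve point maximizing `TPR - slope * FPR` (equivalently, minimizing
#' the expected misclassification cost); exact ties resolve to the smallest
#' FPR.
#'
#' @param curve a [ROCCurve-class].
#' @param slope iso-performance slope, see [isoSlope()].
#' @return List with `fpr`, `tpr`, `threshold`.
#' @export
costOptimalPoint <- function(curve, slope) {
  obj <- curve@tpr - slope * curve@fpr
  best <- which(obj >= max(obj) - 1e-12)
  best <- best[which.min(curve@fpr[best])]
  list(fpr = curve@fpr[best], tpr = curve@tpr[best],
       threshold = curve@thresholds[best])
}

#' Expected misclassification cost of an operating point
#'
#' `C_FP * n * FPR + C_FN * p * (1 - TPR)`.
#'
#' @param point list with `fpr` and `tpr` (as from [costOptimalPoint()]).
#' @param spec a [CostSpec-class].
#' @return Numeric cost.
#' @export
expectedCost <- function(point, spec)
  spec@cFP * spec@n * point$fpr + spec@cFN * spec@p * (1 - point$tpr)

#' Paired contingency table of two classifiers
#'
#' Counts windows by the joint correctness of two binary prediction vectors
#' against the shared labels: both correct (a), only A correct (b), only B
#' correct (c), both wrong (d).
#'
#' @param predsA,predsB binary/label predictions of the two approaches.
#' @param labels true labels.
#' @return A [ContingencyTable-class].
#' @export
buildContingency <- function(predsA, predsB, labels) {
  if (length(predsA) != length(predsB) ||
      length(predsA) != length(labels))
    stop("predictions and labels must have equal length")
  y <- .asLabel01(labels)
  okA <- .asLabel01(predsA) == y
  okB <- .asLabel01(predsB) == y
  new("ContingencyTable",
      a = sum(okA & okB), b = sum(okA & !okB),
      c = sum(!okA & okB), d = sum(!okA & !okB))
}

#' McNemar test on discordant predictions
#'
#' Two-sided exact binomial test on the discordant counts (b, c) when
#' b + c < 25, otherwise the chi-square approximation with continuity
#' correction; the p-value is capped at 1.  With no discordant windows the
#' test is uninformative and returns p = 1 with a warning.
#'
#' @param table a [ContingencyTable-class].
#' @return Numeric p-value.
#' @export
#' @examples
#' mcnemarTest(buildContingency(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1)))
mcnemarTest <- function(table) {
  b <- table@b; c <- table@c
  if (b + c == 0L) {
    warning("no discordant windows; McNemar test is uninformative")
    return(1)
  }
  if (b + c < 25L) {
    min(1, 2 * pbinom(min(b, c), b + c, 0.5))
  } else {
    stat <- (abs(b - c) - 1)^2 / (b + c)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
}
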