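## ROC machinery with pinned tie and step semantics.

.asLabel01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% .LABEL_LEVELS
    if (any(bad)) stop("labels must be 'sufficient' or 'insufficient'")
    return(as.integer(labels == "sufficient"))
  }
  as.integer(labels != 0)
}

#' Empirical ROC curve
#'
#' Sweeps the distinct score values as thresholds (predict positive when
#' score >= threshold), grouping ties, and prepends the (0, 0) endpoint.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels "sufficient"/"insufficient" (or 0/1); both classes required.
#' @return A [ROCCurve-class].
#' @export
#' @examples
#' rocCurve(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
rocCurve <- function(scores, labels) {
  y <- .asLabel01(labels)
  if (length(scores) != length(y)) stop("scores and labels must align")
  P <- sum(y == 1L); N <- sum(y == 0L)
  if (P == 0L || N == 0L)
    stop("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  firsts <- which(!duplicated(s))
  tp <- cumsum(yy); fp <- cumsum(1 - yy)
  last <- c(firsts[-1] - 1L, length(s))  # last index of each tie group
  new("ROCCurve",
      thresholds = c(Inf, s[last]),
      fpr = c(0, fp[last] / N),
      tpr = c(0, tp[last] / P))
}

#' Area under the ROC curve
#'
#' Trapezoidal area; equal to the pairwise probability that a positive
#' window outscores a negative one, counting ties as one half.
#'
#' @param curve a [ROCCurve-class].
#' @return Numeric in \[0, 1\].
#' @export
auroc <- function(curve) {
  sum(diff(curve@fpr) * (head(curve@tpr, -1) + tail(curve@tpr, -1)) / 2)
}

#' Sensitivity at a bounded false-positive rate
#'
#' The maximal TPR over achievable operating points with FPR at or below
#' `fpr0`; no interpolation, since an interpolated point corresponds to no
#' realizable threshold.  Returns 0 when only (0, 0) qualifies.
#'
#' @param curve a [ROCCurve-class].
#' @param fpr0 target bound, 0 < fpr0 < 1.
#' @return Numeric TPR.
#' @export
tprAtFpr <- function(curve, fpr0) {
  stopifnot(fpr0 > 0, fpr0 < 1)
  ok <- curve@fpr <= fpr0 + 1e-12
  if (!any(ok)) return(0)
  max(curve@tpr[ok])
}

#' Specificity at a bounded false-negative rate
#'
#' Symmetric counterpart of [tprAtFpr()]: the maximal TNR (1 - FPR) over
#' points with FNR (1 - TPR) at or below `fnr0`.
#'
#' @param curve a [ROCCurve-class].
#' @param fnr0 target bound, 0 < fnr0 < 1.
#' @return Numeric TNR.
#' @export
tnrAtFnr <- function(curve, fnr0) {
  stopifnot(fnr0 > 0, fnr0 < 1)
  ok <- (1 - curve@tpr) <= fnr0 + 1e-12
  if (!any(ok)) return(0)
  max(1 - curve@fpr[ok])
}

#' Vertically averaged ROC with standard-error band
#'
#' Each curve is evaluated on a fixed FPR grid as a step function (the
#' maximal achievable TPR at FPR <= grid point); the mean and the standard
#' error of the mean (SD / sqrt(k)) are taken pointwise across curves.
#'
#' @param curves list of [ROCCurve-class] (>= 2).
#' @param step grid spacing, default 0.001.
#' @return A [MeanROC-class].
#' @export
meanROC <- function(curves, step = 0.001) {
  stopifnot(length(curves) >= 2L)
  grid <- seq(0, 1, by = step)
  tprAt <- vapply(curves, function(cv)
    vapply(grid, function(g) max(cv@tpr[cv@fpr <= g + 1e-12]), numeric(1)),
    numeric(length(grid)))
  new("MeanROC", grid = grid,
      meanTpr = rowMeans(tprAt),
      stderr = apply(tprAt, 1, sd) / sqrt(length(curves)),
      nCurves = length(curves))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes, 0 <= k <= n.
#' @param n trials, > 0.
#' @param conf confidence level, default 0.95.
#' @return Numeric `c(lo, hi)`.
#' @export
#' @examples
#' wilsonInterval(50, 100)
wilsonInterval <- function(k, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}
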