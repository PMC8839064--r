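## Personal baselines: sufficiency targets from the stable period, and the
## median / 90%-range normalization factors.

#' Per-subject sufficiency targets
#'
#' Arterial-pressure and SvO2 targets derived from the subject's own stable
#' period: target = stable mean - kSd * stable SD.
#'
#' @slot apTarget mmHg.
#' @slot svo2Target percent.
#' @slot kSd the multiplier used to build them.
#' @export
setClass("SufficiencyTargets", representation(
  apTarget = "numeric", svo2Target = "numeric", kSd = "numeric"
))

setMethod("show", "SufficiencyTargets", function(object) {
  cat(sprintf("SufficiencyTargets: AP > %.2f mmHg, SvO2 > %.2f %% (kSd = %g)\n",
              object@apTarget, object@svo2Target, object@kSd))
})

#' Compute a subject's sufficiency targets from its stable period
#'
#' Each target is the stable-period mean minus `kSd` standard deviations of
#' the same channel, so that resuscitation counts as complete once the vitals
#' have returned to the neighbourhood of the personal baseline.  At least
#' 60 s of stable data are required (samples are assumed to be at >= 1 Hz).
#'
#' @param apStable,svo2Stable numeric samples of the invasive arterial
#'   pressure and SvO2 channels during the stable stage.
#' @param kSd non-negative multiplier, default 1.
#' @return A [SufficiencyTargets-class].
#' @export
#' @examples
#' computeTargets(rnorm(300, 80, 5), rnorm(300, 70, 3))
computeTargets <- function(apStable, svo2Stable, kSd = 1) {
  if (length(apStable) == 0L || length(svo2Stable) == 0L)
    stop("empty stable period: targets are undefined")
  if (length(apStable) < 60 || length(svo2Stable) < 60)
    stop("need at least 60 s of stable data to compute targets")
  new("SufficiencyTargets",
      apTarget = mean(apStable) - kSd * sd(apStable),
      svo2Target = mean(svo2Stable) - kSd * sd(svo2Stable),
      kSd = kSd)
}

#' Label a 2-min assessment segment
#'
#' A segment is `"sufficient"` iff the segment means of arterial pressure and
#' SvO2 are both strictly above their targets, `"insufficient"` otherwise
#' (values exactly at the target do not qualify).
#'
#' @param apMean,svo2Mean segment means of the invasive channels.
#' @param targets a [SufficiencyTargets-class].
#' @return `"sufficient"` or `"insufficient"`.
#' @export
labelSegment <- function(apMean, svo2Mean, targets) {
  if (is.na(apMean) || is.na(svo2Mean))
    stop("labeling requires both invasive channels")
  if (apMean > targets@apTarget && svo2Mean > targets@svo2Target)
    "sufficient" else "insufficient"
}

## type-7 (linear interpolation) quantiles, pinned for exact tests
.q <- function(x, p) unname(quantile(x, p, type = 7, na.rm = TRUE))

#' Fit a subject's normalization factors from its stable windows
#'
#' For each feature, `m` is the median and `r` the 90% range (95th minus 5th
#' percentile, linear-interpolation quantiles) over the subject's stable-stage
#' windows.  A degenerate feature with zero range falls back to
#' `max(stable SD, 1e-9)` with a warning, since division by a zero range is
#' undefined.
#'
#' @param x either a windows-by-42 numeric matrix of stable-stage feature
#'   rows, or a [SuffFeatureSet-class] (then `subject` selects whose stable
#'   windows are used).
#' @param subject subject id, required when `x` is a feature set.
#' @return A [NormalizationFactors-class].
#' @export
setGeneric("fitNormalizationFactors",
           function(x, subject = NULL) standardGeneric("fitNormalizationFactors"))

#' @rdname fitNormalizationFactors
#' @export
setMethod("fitNormalizationFactors", "matrix", function(x, subject = NULL) {
  if (nrow(x) < 10L)
    stop("need at least 10 stable-stage windows to fit normalization factors")
  if (!identical(colnames(x), suffFeatureNames()))
    stop("columns must be the canonical features, in order")
  m <- apply(x, 2, median, na.rm = TRUE)
  r <- apply(x, 2, function(col) .q(col, 0.95) - .q(col, 0.05))
  if (any(bad <- (!is.finite(r) | r <= 0))) {
    warning("zero or undefined 90% range for ",
            paste(colnames(x)[bad], collapse = ", "),
            "; falling back to the stable SD")
    fb <- pmax(apply(x[, bad, drop = FALSE], 2, sd, na.rm = TRUE), 1e-9)
    fb[!is.finite(fb)] <- 1e-9
    r[bad] <- fb
  }
  m[!is.finite(m)] <- 0
  new("NormalizationFactors",
      subjectId = if (is.null(subject)) "" else as.character(subject),
      m = m, r = r)
})

#' @rdname fitNormalizationFactors
#' @export
setMethod("fitNormalizationFactors", "SuffFeatureSet", function(x, subject) {
  info <- colData(x)
  keep <- info$subject_id == subject & info$stage == "stable"
  fitNormalizationFactors(featureValues(x[, keep]), subject = subject)
})

#' Apply personal-baseline normalization
#'
#' Element-wise `(X - m) / r` per feature.  Because the factors are fitted
#' per subject, any per-feature affine transform `a * X + b` of a subject's
#' raw data (a > 0) is absorbed: its factors become `(a m + b, a r)` and the
#' normalized data are unchanged.  This absorption is the mechanism that
#' removes inter-subject heterogeneity.
#'
#' @param x a windows-by-42 matrix or a [SuffFeatureSet-class].
#' @param factors a [NormalizationFactors-class]; column alignment with the
#'   canonical ordering is enforced.
#' @return Same shape as `x`, normalized.
#' @export
setGeneric("applyNormalization",
           function(x, factors) standardGeneric("applyNormalization"))

#' @rdname applyNormalization
#' @export
setMethod("applyNormalization", "matrix", function(x, factors) {
  if (!identical(colnames(x), names(factors@m)))
    stop("feature columns are misaligned with the normalization factors")
  sweep(sweep(x, 2, factors@m, "-"), 2, factors@r, "/")
})

#' @rdname applyNormalization
#' @export
setMethod("applyNormalization", "SuffFeatureSet", function(x, factors) {
  out <- x
  SummarizedExperiment::assay(out, "features") <-
    t(applyNormalization(featureValues(x), factors))
  out
})
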