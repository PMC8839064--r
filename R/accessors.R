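## Generics, accessors and show methods.

#' @rdname SuffFeatureSet-class
#' @param object,x an object.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @describeIn SuffFeatureSet-class windows x 42 feature matrix.
#' @export
setMethod("featureValues", "SuffFeatureSet", function(x) t(assay(x, "features")))

#' @rdname SuffFeatureSet-class
#' @export
setGeneric("windowInfo", function(x) standardGeneric("windowInfo"))

#' @describeIn SuffFeatureSet-class per-window metadata as a data.frame.
#' @export
setMethod("windowInfo", "SuffFeatureSet", function(x)
  as.data.frame(colData(x)))

#' @rdname SuffFeatureSet-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @describeIn SuffFeatureSet-class unique subject identifiers, in order of
#'   appearance.
#' @export
setMethod("subjectIds", "SuffFeatureSet", function(x)
  unique(colData(x)$subject_id))

#' @rdname NormalizationFactors-class
#' @param x a `NormalizationFactors`.
#' @export
setGeneric("nfMedians", function(x) standardGeneric("nfMedians"))

#' @describeIn NormalizationFactors-class the median vector m.
#' @export
setMethod("nfMedians", "NormalizationFactors", function(x) x@m)

#' @rdname NormalizationFactors-class
#' @export
setGeneric("nfRanges", function(x) standardGeneric("nfRanges"))

#' @describeIn NormalizationFactors-class the 90%-range vector r.
#' @export
setMethod("nfRanges", "NormalizationFactors", function(x) x@r)

#' @rdname OAPredictor-class
#' @param x an `OAPredictor`.
#' @export
setGeneric("tauStar", function(x) standardGeneric("tauStar"))

#' @describeIn OAPredictor-class the selected binarization threshold.
#' @export
setMethod("tauStar", "OAPredictor", function(x) x@tauStar)

#' @describeIn ThresholdSearch-class the selected binarization threshold.
#' @export
setMethod("tauStar", "ThresholdSearch", function(x) x@tauStar)

#' @rdname OAPredictor-class
#' @export
setGeneric("factorBank", function(x) standardGeneric("factorBank"))

#' @describeIn OAPredictor-class the list of training-subject normalization
#'   factors.
#' @export
setMethod("factorBank", "OAPredictor", function(x) x@factorBank)

#' @rdname ROCCurve-class
#' @param x a `ROCCurve`.
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @describeIn ROCCurve-class operating points as a data.frame
#'   (threshold, fpr, tpr).
#' @export
setMethod("rocPoints", "ROCCurve", function(x)
  data.frame(threshold = x@thresholds, fpr = x@fpr, tpr = x@tpr))

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSubjects, "subjects, seed", object@seed, "\n")
  cat("  stages: stable", object@stableDuration, "s | bleed to MAP <",
      object@bleedMapStop, "mmHg | waiting", object@waitingDuration,
      "s | resuscitation (bolus", object@bolusDuration, "s)\n")
  cat("  heterogeneity: shift SD", object@subjectShiftSd,
      ", log-scale SD", object@subjectScaleSd, "\n")
})

setMethod("show", "SubjectRecord", function(object) {
  cat("SubjectRecord", object@subjectId, "@", object@fs, "Hz\n")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  st <- object@stages
  cat("  stages:", paste(sprintf("%s[%g-%g]", st$stage, st$start, st$end),
                         collapse = " "), "\n")
  cat("  assessments:", length(object@assessmentTimes), "\n")
})

setMethod("show", "SuffFeatureSet", function(object) {
  info <- colData(object)
  cat("SuffFeatureSet:", ncol(object), "windows x", nrow(object),
      "features;", length(unique(info$subject_id)), "subjects\n")
  cat("  stages:", paste(names(table(info$stage)), table(info$stage),
                         sep = "=", collapse = " "), "\n")
  cat("  labels:", paste(names(table(info$label)), table(info$label),
                         sep = "=", collapse = " "), "\n")
})

setMethod("show", "NormalizationFactors", function(object) {
  cat("NormalizationFactors for", object@subjectId, "(", length(object@m),
      "features )\n")
})

setMethod("show", "OAPredictor", function(object) {
  cat("OAPredictor:", length(object@factorBank),
      "voting baselines, tau* =", format(object@tauStar, digits = 4), "\n")
})

setMethod("show", "ROCCurve", function(object) {
  cat("ROCCurve:", length(object@fpr), "operating points, AUROC =",
      format(auroc(object), digits = 4), "\n")
})

setMethod("show", "ContingencyTable", function(object) {
  m <- matrix(c(object@a, object@b, object@c, object@d), 2, 2, byrow = TRUE,
              dimnames = list(c("A correct", "A wrong"),
                              c("B correct", "B wrong")))
  print(m)
})
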