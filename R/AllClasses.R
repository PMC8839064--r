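## S4 class definitions and validity.  Accessors live in accessors.R.

#' Cohort simulation configuration
#'
#' Holds every tunable of the synthetic hemorrhage/resuscitation protocol:
#' stage durations, the bleeding stop pressure, the bolus/assessment cadence,
#' population-level vital-sign locations and scales, the dispersion of the
#' per-subject affine heterogeneity, and noise levels.  Construct with
#' [cohortConfig()], which documents all defaults.
#'
#' @slot nSubjects integer, number of subjects (>= 2; LOSO is undefined below
#'   that).
#' @slot stableDuration,waitingDuration seconds (defaults 1800 each: the
#'   protocol stabilizes for 30 min and waits 30 min after bleeding).
#' @slot bleedMapStop mmHg; bleeding ends when latent MAP first drops below
#'   this (default 40).
#' @slot bleedSensitivity mmHg/s rate of latent MAP decline while bleeding.
#' @slot bolusDuration seconds per fluid bolus (default 360).
#' @slot bolusResponse latent severity restored per bolus (fraction of the
#'   full stable-to-shock span).
#' @slot assessmentInterval,assessmentIntervalBolus seconds between
#'   sufficiency assessments without / with an intervening bolus (300 / 660).
#' @slot maxAssessments integer cap guaranteeing termination.
#' @slot populationMeans,populationSds named numeric over
#'   c("map","hr","svo2","svv","ppv").
#' @slot subjectShiftSd,subjectScaleSd dispersion of per-subject additive
#'   shifts (in population-SD units) and of log scale factors.
#' @slot noiseSd latent AR(1) noise, as a fraction of each vital's population
#'   SD.
#' @slot obsNoiseSd additive waveform observation noise.
#' @slot featureNoiseSd within-class feature SD multiplier (feature tier).
#' @slot rrJitterSd fractional beat-to-beat R-R jitter.
#' @slot respiratoryRate Hz, modulates PPV/SVV and pulse amplitudes.
#' @slot waveformFs Hz sampling rate of waveform channels (>= 100).
#' @slot kSd target multiplier: target = stable mean - kSd * stable SD.
#' @slot segmentsPerStage named integer, 2-min training segments sampled from
#'   each of stable/bleeding/waiting.
#' @slot seed integer master seed.
#' @export
setClass("CohortConfig", representation(
  nSubjects = "integer",
  stableDuration = "numeric",
  waitingDuration = "numeric",
  bleedMapStop = "numeric",
  bleedSensitivity = "numeric",
  bolusDuration = "numeric",
  bolusResponse = "numeric",
  assessmentInterval = "numeric",
  assessmentIntervalBolus = "numeric",
  maxAssessments = "integer",
  populationMeans = "numeric",
  populationSds = "numeric",
  subjectShiftSd = "numeric",
  subjectScaleSd = "numeric",
  noiseSd = "numeric",
  obsNoiseSd = "numeric",
  featureNoiseSd = "numeric",
  rrJitterSd = "numeric",
  respiratoryRate = "numeric",
  waveformFs = "numeric",
  kSd = "numeric",
  segmentsPerStage = "integer",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  durs <- c(object@stableDuration, object@waitingDuration,
            object@bolusDuration, object@assessmentInterval,
            object@assessmentIntervalBolus)
  if (any(!is.finite(durs)) || any(durs <= 0))
    msg <- c(msg, "all durations must be positive")
  vit <- c("map", "hr", "svo2", "svv", "ppv")
  if (!identical(names(object@populationMeans), vit) ||
      !identical(names(object@populationSds), vit))
    msg <- c(msg, "populationMeans/populationSds must be named map,hr,svo2,svv,ppv")
  else if (object@bleedMapStop >= object@populationMeans[["map"]])
    msg <- c(msg, "bleedMapStop must lie below the population mean MAP")
  if (object@waveformFs < 100)
    msg <- c(msg, "waveformFs must be at least 100 Hz")
  if (object@subjectScaleSd < 0 || object@subjectShiftSd < 0)
    msg <- c(msg, "heterogeneity dispersions must be non-negative")
  if (!all(c("stable", "bleeding", "waiting") %in%
           names(object@segmentsPerStage)))
    msg <- c(msg, "segmentsPerStage must name stable, bleeding and waiting")
  if (length(msg)) msg else TRUE
})

#' Per-subject simulation parameters
#'
#' One subject's fixed heterogeneity: an affine (shift, scale) pair per
#' tracked quantity, drawn once and held for the subject's lifetime, plus the
#' subject's bleeding sensitivity and bolus response.  Shifts are expressed in
#' population-SD units; scales are multiplicative and positive.
#'
#' @slot subjectId character.
#' @slot shifts,scales named numeric, one entry per tracked quantity.
#' @slot bleedSensitivity mmHg/s.
#' @slot bolusResponse severity units restored per bolus.
#' @export
setClass("SubjectParams", representation(
  subjectId = "character",
  shifts = "numeric",
  scales = "numeric",
  bleedSensitivity = "numeric",
  bolusResponse = "numeric"
))

setValidity("SubjectParams", function(object) {
  msg <- character()
  if (!identical(names(object@shifts), names(object@scales)))
    msg <- c(msg, "shifts and scales must share names")
  if (any(object@scales <= 0))
    msg <- c(msg, "scale factors must be positive")
  if (length(msg)) msg else TRUE
})

#' One subject's annotated multichannel recording
#'
#' Waveform channels (ECG, PPG, arterial pressure, SvO2) at `fs` Hz, the
#' device beat-to-beat series (MAP, SVV, PPV), contiguous stage annotations in
#' protocol order (stable, bleeding, waiting, resuscitation), assessment
#' timestamps, and -- for simulated records -- the ground truth (latent vitals
#' trajectory, true beat and PPG-foot times, the generating parameters).
#'
#' @slot subjectId character.
#' @slot fs sampling rate, Hz.
#' @slot channels named list of numeric vectors (ecg, ppg, ap, svo2).
#' @slot beatSeries data.frame with columns time, map, svv, ppv.
#' @slot stages data.frame with columns stage, start, end (seconds).
#' @slot assessmentTimes numeric, seconds; all inside resuscitation.
#' @slot truth list; empty for real recordings.
#' @export
setClass("SubjectRecord", representation(
  subjectId = "character",
  fs = "numeric",
  channels = "list",
  beatSeries = "data.frame",
  stages = "data.frame",
  assessmentTimes = "numeric",
  truth = "list"
))

setValidity("SubjectRecord", function(object) {
  msg <- character()
  st <- object@stages
  if (!all(c("stage", "start", "end") %in% names(st)))
    return("stages must have columns stage, start, end")
  if (nrow(st) > 1 && any(abs(st$start[-1] - st$end[-nrow(st)]) > 1e-6))
    msg <- c(msg, "stages must be contiguous and non-overlapping")
  proto <- c("stable", "bleeding", "waiting", "resuscitation")
  if (!all(st$stage %in% proto) ||
      any(diff(match(st$stage, proto)) < 0))
    msg <- c(msg, "stages must follow protocol order")
  if (length(object@assessmentTimes)) {
    res <- st[st$stage == "resuscitation", , drop = FALSE]
    if (nrow(res) == 0L ||
        any(object@assessmentTimes < res$start[1] - 1e-6) ||
        any(object@assessmentTimes > res$end[nrow(res)] + 1e-6))
      msg <- c(msg, "assessment times must fall in the resuscitation stage")
  }
  if (length(object@channels)) {
    total <- max(st$end)
    n <- vapply(object@channels, length, integer(1))
    if (any(abs(n - total * object@fs) > object@fs))
      msg <- c(msg, "channel lengths inconsistent with fs and total duration")
  }
  if (length(msg)) msg else TRUE
})

#' Window-level feature container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"features"`
#' (42 canonical features x windows) and per-window metadata in `colData`:
#' `subject_id`, `segment_id`, `window_index`, `stage`, `label`, `t_start_s`.
#' Rows are fixed to [suffFeatureNames()]; at most 11 windows share a 120-s
#' parent segment and all windows of a segment carry its sufficiency label.
#'
#' @export
setClass("SuffFeatureSet", contains = "SummarizedExperiment")

setValidity("SuffFeatureSet", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  if (!identical(rownames(object), suffFeatureNames()))
    msg <- c(msg, "rows must be the canonical 42 features, in order")
  need <- c("subject_id", "segment_id", "window_index", "stage", "label",
            "t_start_s")
  if (!all(need %in% colnames(colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Personal-baseline normalization factors
#'
#' A subject's per-feature stable-stage median `m` and 90% range `r` (95th
#' minus 5th percentile), the pair (m, r) used to normalize data as
#' (X - m) / r.
#'
#' @slot subjectId character.
#' @slot m,r named numeric of length 42 in canonical feature order; r > 0.
#' @export
setClass("NormalizationFactors", representation(
  subjectId = "character", m = "numeric", r = "numeric"
))

setValidity("NormalizationFactors", function(object) {
  msg <- character()
  if (!identical(names(object@m), suffFeatureNames()) ||
      !identical(names(object@r), suffFeatureNames()))
    msg <- c(msg, "m and r must be aligned to the canonical feature order")
  if (any(!is.finite(object@r)) || any(object@r <= 0))
    msg <- c(msg, "all ranges r must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Fitted window scorer
#'
#' Wraps a fitted probability forest together with everything needed to score
#' new windows deterministically: the feature ordering, the training-set
#' medians used to impute missing features, and the seed/hyperparameters.
#' `scoreWindows()` returns the probability of the positive (sufficient)
#' class, in \[0, 1\].
#'
#' @slot forest the fitted ranger object.
#' @slot featureNames character.
#' @slot imputeMedians named numeric, training medians per feature.
#' @slot numTrees,seed integers.
#' @slot maxDepth,minNodeSize,mtry integers (0 = unlimited depth).
#' @export
setClass("ScorerModel", representation(
  forest = "ANY",
  featureNames = "character",
  imputeMedians = "numeric",
  numTrees = "integer",
  maxDepth = "integer",
  minNodeSize = "integer",
  mtry = "integer",
  seed = "integer"
))

#' Threshold search result
#'
#' Candidate binarization thresholds (drawn from the unique validation vote
#' scores of the inner leave-one-subject-out folds), the mean Pearson
#' correlation each candidate attains across validation subjects, and the
#' selected threshold `tauStar` (smallest maximizer).
#'
#' @slot candidates,meanCorrelation numeric, parallel vectors.
#' @slot tauStar numeric scalar.
#' @export
setClass("ThresholdSearch", representation(
  candidates = "numeric", meanCorrelation = "numeric", tauStar = "numeric"
))

setValidity("ThresholdSearch", function(object) {
  if (length(object@candidates) != length(object@meanCorrelation))
    return("candidates and meanCorrelation must be parallel")
  ok <- is.finite(object@meanCorrelation)
  if (any(ok) &&
      !isTRUE(all.equal(max(object@meanCorrelation[ok]),
                        object@meanCorrelation[which(object@candidates ==
                                                       object@tauStar)][1])))
    return("tauStar must attain the maximal mean correlation")
  TRUE
})

#' Optimized-Aggregation-of-Predictions predictor
#'
#' The trained scorer (fit on all training subjects' self-normalized windows),
#' the bank of training-subject normalization factors, and the binarization
#' threshold selected by the inner-loop correlation search.  Prediction for a
#' baseline-less subject normalizes its raw windows with every bank entry,
#' scores, binarizes at `tauStar` and reports the positive-vote fraction.
#'
#' @slot scorer a [ScorerModel-class].
#' @slot factorBank non-empty list of [NormalizationFactors-class].
#' @slot tauStar numeric in \[0, 1\].
#' @slot search the [ThresholdSearch-class] that produced tauStar.
#' @slot searchK,seed integers.
#' @export
setClass("OAPredictor", representation(
  scorer = "ScorerModel",
  factorBank = "list",
  tauStar = "numeric",
  search = "ThresholdSearch",
  searchK = "integer",
  seed = "integer"
))

setValidity("OAPredictor", function(object) {
  msg <- character()
  if (length(object@factorBank) == 0L)
    msg <- c(msg, "factorBank must be non-empty")
  if (!all(vapply(object@factorBank, is, logical(1), "NormalizationFactors")))
    msg <- c(msg, "factorBank entries must be NormalizationFactors")
  if (object@tauStar < 0 || object@tauStar > 1)
    msg <- c(msg, "tauStar must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (ties grouped), plus the
#' (0, 0) endpoint; `fpr` and `tpr` are non-decreasing from (0, 0) to (1, 1).
#' FNR and TNR are the complements 1 - tpr and 1 - fpr.
#'
#' @slot thresholds numeric, decreasing, starting at Inf.
#' @slot fpr,tpr numeric, same length.
#' @export
setClass("ROCCurve", representation(
  thresholds = "numeric", fpr = "numeric", tpr = "numeric"
))

setValidity("ROCCurve", function(object) {
  msg <- character()
  if (length(object@fpr) != length(object@tpr) ||
      length(object@fpr) != length(object@thresholds))
    msg <- c(msg, "thresholds, fpr, tpr must be parallel")
  if (any(diff(object@fpr) < -1e-12) || any(diff(object@tpr) < -1e-12))
    msg <- c(msg, "fpr and tpr must be non-decreasing")
  n <- length(object@fpr)
  if (n && (object@fpr[1] != 0 || object@tpr[1] != 0 ||
            abs(object@fpr[n] - 1) > 1e-12 || abs(object@tpr[n] - 1) > 1e-12))
    msg <- c(msg, "curve must run from (0,0) to (1,1)")
  if (length(msg)) msg else TRUE
})

#' Vertically averaged ROC
#'
#' Mean true-positive rate over a fixed false-positive-rate grid, with the
#' per-grid-point standard error of the mean across the input curves.
#'
#' @slot grid,meanTpr,stderr numeric, parallel; grid covers \[0, 1\].
#' @slot nCurves integer.
#' @export
setClass("MeanROC", representation(
  grid = "numeric", meanTpr = "numeric", stderr = "numeric",
  nCurves = "integer"
))

setValidity("MeanROC", function(object) {
  if (any(object@stderr < 0)) return("stderr must be non-negative")
  if (min(object@grid) > 0 || max(object@grid) < 1)
    return("grid must cover [0, 1]")
  TRUE
})

#' Misclassification cost model
#'
#' Class frequencies (p positive / n negative windows) and unit error costs
#' C_FP, C_FN.  The implied iso-performance slope in ROC space is
#' (n / p) * (C_FP / C_FN); see [isoSlope()].
#'
#' @slot p,n positive counts or frequencies.
#' @slot cFP,cFN positive unit costs.
#' @export
setClass("CostSpec", representation(
  p = "numeric", n = "numeric", cFP = "numeric", cFN = "numeric"
))

setValidity("CostSpec", function(object) {
  if (object@p <= 0 || object@n <= 0) return("p and n must be positive")
  if (object@cFP <= 0 || object@cFN <= 0) return("costs must be positive")
  TRUE
})

#' Paired-classifier contingency table
#'
#' Window-level agreement counts for two classifiers on the same windows:
#' `a` both correct, `b` only A correct, `c` only B correct, `d` both wrong.
#'
#' @slot a,b,c,d non-negative integer counts.
#' @export
setClass("ContingencyTable", representation(
  a = "integer", b = "integer", c = "integer", d = "integer"
))

setValidity("ContingencyTable", function(object) {
  v <- c(object@a, object@b, object@c, object@d)
  if (any(v < 0)) return("counts must be non-negative")
  TRUE
})
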