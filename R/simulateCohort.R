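## Cohort-level generators: the waveform tier (full records) and the fast
## feature-level tier used for classifier and evaluation experiments.

.subjectIdFmt <- function(i) sprintf("S%02d", i)

#' Simulate a waveform-tier cohort
#'
#' Draws `nSubjects` independent subjects, each from its own seeded
#' sub-stream of the master seed, and synthesizes full annotated recordings
#' (latent truth, waveform channels, beat series, stage annotations,
#' assessment times).  Fully reproducible from `config`.
#'
#' @param config a [CohortConfig-class].
#' @return Named list of [SubjectRecord-class] objects.
#' @export
#' @examples
#' cfg <- cohortConfig(nSubjects = 2, stableDuration = 240,
#'                     waitingDuration = 120, bleedSensitivity = 0.25,
#'                     seed = 42)
#' rec <- simulateCohort(cfg)[[1]]
simulateCohort <- function(config) {
  if (config@nSubjects < 2L)
    stop("need at least 2 subjects: leave-one-subject-out is undefined")
  set.seed(config@seed)
  seeds <- sample.int(.Machine$integer.max, config@nSubjects)
  recs <- lapply(seq_len(config@nSubjects), function(i) {
    set.seed(seeds[i])
    params <- drawSubjectParams(config, subjectId = .subjectIdFmt(i))
    synthesizeWaveforms(simulateLatent(params, config), params, config)
  })
  names(recs) <- vapply(recs, function(r) r@subjectId, character(1))
  recs
}

## severity -> latent invasive channel samples at 1 Hz for one 2-min segment
.segmentLatent <- function(s, baseMap, baseSvo2, noiseSdAbs, arState) {
  det <- c(map = baseMap - s * (baseMap - .MAP_FLOOR),
           svo2 = baseSvo2 - s * (baseSvo2 - .SVO2_FLOOR))
  mapN <- .arNoise(120, noiseSdAbs[["map"]], arState$map)
  svN <- .arNoise(120, noiseSdAbs[["svo2"]], arState$svo2)
  list(map = det[["map"]] + mapN$x, svo2 = det[["svo2"]] + svN$x,
       state = list(map = mapN$last, svo2 = svN$last))
}

#' Generate a feature-level synthetic cohort
#'
#' The fast tier: emits window-level 42-feature rows directly, skipping
#' waveform synthesis and featurization.  All subjects share one latent
#' class-conditional feature distribution -- each feature responds linearly
#' to the scalar severity state with a fixed physiologically signed loading
#' (see the package vignette) plus unit-SD observation noise -- and each
#' subject then applies its own per-feature affine transform
#' `x -> scale * x + shift * sd`, the heterogeneity that personal-baseline
#' normalization absorbs.  Segments follow the protocol: stable / bleeding /
#' waiting segments at their characteristic severities, then a resuscitation
#' assessment-and-bolus sequence with labels derived from latent AP/SvO2
#' segment means against the subject's stable-period targets.
#'
#' @param config a [CohortConfig-class].
#' @return A [SuffFeatureSet-class]; `metadata()` carries the per-subject
#'   [SubjectParams-class] (ground truth) and the config.
#' @export
#' @examples
#' fs <- generateFeatureCohort(cohortConfig(nSubjects = 4, seed = 3))
#' table(windowInfo(fs)$stage)
generateFeatureCohort <- function(config) {
  if (config@nSubjects < 2L)
    stop("need at least 2 subjects: leave-one-subject-out is undefined")
  fm <- .featureModel()
  fnames <- rownames(fm)
  set.seed(config@seed)
  seeds <- sample.int(.Machine$integer.max, config@nSubjects)
  noiseSdAbs <- config@noiseSd * config@populationSds

  allX <- list(); allInfo <- list(); allParams <- list()
  for (i in seq_len(config@nSubjects)) {
    set.seed(seeds[i])
    sid <- .subjectIdFmt(i)
    params <- drawSubjectParams(config, quantities = fnames, subjectId = sid)
    baseMap <- config@populationMeans[["map"]] +
      rnorm(1, 0, config@populationSds[["map"]])
    baseSvo2 <- config@populationMeans[["svo2"]] +
      rnorm(1, 0, config@populationSds[["svo2"]])

    ## ---- segment plan: severity per segment, protocol order ----
    nS <- config@segmentsPerStage[["stable"]]
    nB <- config@segmentsPerStage[["bleeding"]]
    nW <- config@segmentsPerStage[["waiting"]]
    sev <- c(rep(0, nS),
             seq_len(nB) / (nB + 1),
             rep(1, nW))
    stage <- c(rep("stable", nS), rep("bleeding", nB), rep("waiting", nW))

    ## latent invasive samples + targets
    arState <- list(map = 0, svo2 = 0)
    segLat <- vector("list", length(sev))
    for (k in seq_along(sev)) {
      segLat[[k]] <- .segmentLatent(sev[k], baseMap, baseSvo2, noiseSdAbs,
                                    arState)
      arState <- segLat[[k]]$state
    }
    stabIdx <- which(stage == "stable")
    targets <- computeTargets(
      unlist(lapply(segLat[stabIdx], `[[`, "map")),
      unlist(lapply(segLat[stabIdx], `[[`, "svo2")), kSd = config@kSd)

    ## ---- resuscitation assessment/bolus sequence ----
    s <- 1.0; sufficientRun <- 0L
    repeat {
      lat <- .segmentLatent(s, baseMap, baseSvo2, noiseSdAbs, arState)
      arState <- lat$state
      segLat[[length(segLat) + 1L]] <- lat
      sev <- c(sev, s); stage <- c(stage, "resuscitation")
      lab <- labelSegment(mean(lat$map), mean(lat$svo2), targets)
      if (lab == "sufficient") {
        sufficientRun <- sufficientRun + 1L
        if (sufficientRun >= 2L) break
      } else {
        sufficientRun <- 0L
        s <- max(0, s - params@bolusResponse)
      }
      if (sum(stage == "resuscitation") >= config@maxAssessments) break
    }

    labels <- vapply(segLat, function(l)
      labelSegment(mean(l$map), mean(l$svo2), targets), character(1))

    ## ---- window features: shared latent response, then subject affine ----
    nSeg <- length(sev)
    nWin <- 11L
    sWin <- rep(sev, each = nWin) + rnorm(nSeg * nWin, 0, 0.02)
    z <- outer(sWin, fm[, "loading"]) +
      matrix(rnorm(nSeg * nWin * nrow(fm), 0, config@featureNoiseSd),
             nSeg * nWin, nrow(fm))
    latentX <- sweep(sweep(z, 2, fm[, "sd"], "*"), 2, fm[, "base"], "+")
    x <- sweep(sweep(latentX, 2, params@scales, "*"),
               2, params@shifts * fm[, "sd"], "+")
    colnames(x) <- fnames

    segId <- paste0(sid, "_seg", sprintf("%02d", seq_len(nSeg)))
    info <- data.frame(
      subject_id = sid,
      segment_id = rep(segId, each = nWin),
      window_index = rep(seq_len(nWin), nSeg),
      stage = rep(stage, each = nWin),
      label = rep(labels, each = nWin),
      t_start_s = rep((seq_len(nSeg) - 1) * 600, each = nWin) +
        (rep(seq_len(nWin), nSeg) - 1) * 10)
    allX[[i]] <- x; allInfo[[i]] <- info; allParams[[i]] <- params
  }

  x <- do.call(rbind, allX)
  info <- do.call(rbind, allInfo)
  names(allParams) <- vapply(allParams, function(p) p@subjectId, character(1))
  fs <- SuffFeatureSet(x, info)
  metadata(fs)$subjectParams <- allParams
  metadata(fs)$config <- config
  metadata(fs)$featureOrderHash <- featureOrderHash()
  fs
}

#' Construct a SuffFeatureSet from a feature matrix and window metadata
#'
#' @param features windows-by-42 numeric matrix with canonical column names.
#' @param info data.frame with columns subject_id, segment_id, window_index,
#'   stage, label, t_start_s (one row per window).
#' @return A [SuffFeatureSet-class].
#' @export
SuffFeatureSet <- function(features, info) {
  stopifnot(nrow(features) == nrow(info))
  se <- SummarizedExperiment(
    assays = list(features = t(features)),
    colData = DataFrame(info, row.names = NULL))
  if (nrow(info) > 0L)
    colnames(se) <- paste0(info$segment_id, "_w", info$window_index)
  new("SuffFeatureSet", se)
}
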