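## Record -> windows -> 42-feature vectors.

#' Precompute per-beat series for featurization
#'
#' Runs the fiducial detectors once per record: R peaks from the ECG, PPG
#' foot/peak geometry, per-beat PTT and instantaneous HR, and aligns them
#' with the device beat-to-beat series (MAP, SVV, PPV).  The result feeds
#' [featurizeWindow()] for every window of the record.
#'
#' @param record a [SubjectRecord-class].
#' @return List of per-beat tables, one element per source time base.
#' @export
prepareBeatData <- function(record) {
  fs <- record@fs
  rT <- detectRPeaks(record@channels$ecg, fs)
  fid <- detectPPGFiducials(record@channels$ppg, fs, rT)
  ptt <- computePTT(rT, fid$tFoot)
  hrT <- if (length(rT) > 1L) rT[-1] else numeric(0)
  hrV <- if (length(rT) > 1L) 60 / diff(rT) else numeric(0)
  list(rTimes = rT,
       hr = data.frame(time = hrT, value = hrV),
       ptt = data.frame(time = rT, value = ptt),
       ppg = data.frame(time = fid$tFoot, amp = fid$amp, rise = fid$rise,
                        width = fid$width, area = fid$area, fall = fid$fall),
       device = record@beatSeries)
}

#' Featurize one 20-s window
#'
#' Produces the 42 canonical features for the window `[start, end)`: median /
#' IQR / slope of the five beat-to-beat channels and the five PPG geometry
#' channels (each on its own time base; beat membership is half-open so a
#' beat is never counted by two adjacent windows), plus the 12 HRV scalars
#' from the R-R intervals inside the window.  Windows holding fewer than 3
#' detected beats yield an all-missing vector.
#'
#' @param beatData output of [prepareBeatData()].
#' @param start,end window bounds in seconds (end defaults to start + 20).
#' @return Named numeric of length 42 in canonical order.
#' @export
featurizeWindow <- function(beatData, start, end = start + 20) {
  fnames <- suffFeatureNames()
  out <- stats::setNames(rep(NA_real_, length(fnames)), fnames)
  rIn <- beatData$rTimes[beatData$rTimes >= start & beatData$rTimes < end]
  if (length(rIn) < 3L) return(out)

  aggInto <- function(prefix, times, values) {
    inW <- times >= start & times < end
    a <- aggregateBeatSeries(values[inW], times[inW])
    out[paste(prefix, c("median", "iqr", "slope"), sep = "_")] <<- a
  }
  dev <- beatData$device
  aggInto("map", dev$time, dev$map)
  aggInto("svv", dev$time, dev$svv)
  aggInto("ppv", dev$time, dev$ppv)
  aggInto("hr", beatData$hr$time, beatData$hr$value)
  aggInto("ptt", beatData$ptt$time, beatData$ptt$value)
  ppg <- beatData$ppg
  for (ch in c("amp", "rise", "width", "area", "fall"))
    aggInto(paste0("ppg_", ch), ppg$time, ppg[[ch]])
  out[.HRV_NAMES] <- computeHRVMetrics(diff(rIn))
  out
}

#' Sample and label 2-min segments from a record
#'
#' Evenly samples `segmentsPerStage` 2-min segments from each of the stable,
#' bleeding and waiting stages, and takes the 2-min segment preceding every
#' sufficiency assessment in the resuscitation stage.  Each segment is
#' labeled from the means of the invasive AP and SvO2 channels against the
#' subject's stable-period targets (strictly above both = sufficient).
#'
#' @param record a [SubjectRecord-class] with `ap` and `svo2` channels.
#' @param segmentsPerStage named integer (stable, bleeding, waiting).
#' @param kSd target multiplier, default 1.
#' @return data.frame: segment_id, start, end, stage, label, apMean,
#'   svo2Mean.
#' @export
sampleSegments <- function(record,
                           segmentsPerStage = c(stable = 2L, bleeding = 1L,
                                                waiting = 1L),
                           kSd = 1) {
  fs <- record@fs
  st <- record@stages
  chanMean <- function(ch, a, b) {
    i0 <- floor(a * fs) + 1L; i1 <- min(length(record@channels[[ch]]),
                                        floor(b * fs))
    mean(record@channels[[ch]][i0:i1])
  }
  stab <- st[st$stage == "stable", ]
  i0 <- floor(stab$start * fs) + 1L; i1 <- floor(stab$end * fs)
  targets <- computeTargets(record@channels$ap[i0:i1] [
                              seq(1, i1 - i0 + 1, by = max(1, fs / 2))],
                            record@channels$svo2[i0:i1][
                              seq(1, i1 - i0 + 1, by = max(1, fs / 2))],
                            kSd = kSd)

  segs <- list()
  for (sg in c("stable", "bleeding", "waiting")) {
    nSeg <- segmentsPerStage[[sg]]
    row <- st[st$stage == sg, ]
    dur <- row$end - row$start
    if (dur < 120) {
      warning("stage ", sg, " shorter than one 2-min segment; skipped")
      next
    }
    starts <- if (nSeg == 1L) row$start + (dur - 120) / 2 else
      row$start + (seq_len(nSeg) - 1) * (dur - 120) / (nSeg - 1)
    segs[[sg]] <- data.frame(start = starts, end = starts + 120, stage = sg)
  }
  if (length(record@assessmentTimes))
    segs$resuscitation <- data.frame(start = record@assessmentTimes - 120,
                                     end = record@assessmentTimes,
                                     stage = "resuscitation")
  segs <- do.call(rbind, segs)
  rownames(segs) <- NULL
  segs$apMean <- mapply(function(a, b) chanMean("ap", a, b),
                        segs$start, segs$end)
  segs$svo2Mean <- mapply(function(a, b) chanMean("svo2", a, b),
                          segs$start, segs$end)
  segs$label <- mapply(function(a, s) labelSegment(a, s, targets),
                       segs$apMean, segs$svo2Mean)
  segs$segment_id <- paste0(record@subjectId, "_seg",
                            sprintf("%02d", seq_len(nrow(segs))))
  segs[, c("segment_id", "start", "end", "stage", "label",
           "apMean", "svo2Mean")]
}

#' Build a feature matrix from one subject's record
#'
#' Extracts the 11 moving windows of every labeled 2-min segment and
#' featurizes each; all windows of a segment inherit its sufficiency label.
#'
#' @param record a [SubjectRecord-class].
#' @param segments labeled segments as from [sampleSegments()].
#' @return A [SuffFeatureSet-class] (one column per window).
#' @export
buildFeatureMatrix <- function(record, segments) {
  total <- max(record@stages$end)
  if (nrow(segments) &&
      (any(segments$start < -1e-9) || any(segments$end > total + 1e-9)))
    stop("segment outside the recording")
  fnames <- suffFeatureNames()
  if (nrow(segments) == 0L) {
    return(SuffFeatureSet(
      matrix(numeric(0), 0, 42, dimnames = list(NULL, fnames)),
      data.frame(subject_id = character(0), segment_id = character(0),
                 window_index = integer(0), stage = character(0),
                 label = character(0), t_start_s = numeric(0))))
  }
  beatData <- prepareBeatData(record)
  rows <- list(); info <- list()
  for (i in seq_len(nrow(segments))) {
    w <- extractWindows(segments$start[i], segments$end[i])
    if (nrow(w) == 0L) next
    x <- t(vapply(seq_len(nrow(w)), function(j)
      featurizeWindow(beatData, w$start[j], w$end[j]), numeric(42)))
    rows[[i]] <- x
    info[[i]] <- data.frame(subject_id = record@subjectId,
                            segment_id = segments$segment_id[i],
                            window_index = seq_len(nrow(w)),
                            stage = segments$stage[i],
                            label = segments$label[i],
                            t_start_s = w$start)
  }
  x <- do.call(rbind, rows)
  colnames(x) <- fnames
  SuffFeatureSet(x, do.call(rbind, info))
}

#' Featurize a whole waveform cohort
#'
#' Applies [sampleSegments()] and [buildFeatureMatrix()] to every record and
#' binds the results into one cohort-level feature set.
#'
#' @param records list of [SubjectRecord-class].
#' @param segmentsPerStage,kSd passed to [sampleSegments()].
#' @return A [SuffFeatureSet-class].
#' @export
featurizeCohort <- function(records,
                            segmentsPerStage = c(stable = 2L, bleeding = 1L,
                                                 waiting = 1L),
                            kSd = 1) {
  sets <- lapply(records, function(r)
    buildFeatureMatrix(r, sampleSegments(r, segmentsPerStage, kSd)))
  out <- do.call(SummarizedExperiment::cbind, sets)
  new("SuffFeatureSet", out)
}
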