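## Plain-text round-tripping of every pipeline artifact.  CSV everywhere for
## inspectability; manifests as JSON.

#' Write / read a feature matrix as CSV
#'
#' Fixed layout: the six metadata columns then the 42 canonical feature
#' columns.  Reading verifies the feature-order hash implied by the header.
#'
#' @param fset a [SuffFeatureSet-class].
#' @param path CSV file path.
#' @return `readFeatureMatrix` returns a [SuffFeatureSet-class];
#'   `writeFeatureMatrix` returns `path` invisibly.
#' @export
writeFeatureMatrix <- function(fset, path) {
  df <- cbind(windowInfo(fset), as.data.frame(featureValues(fset)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- c("subject_id", "segment_id", "window_index", "stage", "label",
            "t_start_s")
  if (!identical(colnames(df), c(meta, suffFeatureNames())))
    stop("feature CSV header does not match the canonical feature ordering")
  SuffFeatureSet(as.matrix(df[, suffFeatureNames(), drop = FALSE]),
                 df[, meta])
}

#' Write / read a normalization-factor bank as CSV
#'
#' One row per subject: subject_id, then m_1..m_42, then r_1..r_42 in
#' canonical feature order.
#'
#' @param bank list of [NormalizationFactors-class].
#' @param path CSV file path.
#' @export
writeFactorBank <- function(bank, path) {
  fn <- suffFeatureNames()
  df <- do.call(rbind, lapply(bank, function(f)
    data.frame(subject_id = f@subjectId,
               t(stats::setNames(f@m, paste0("m_", fn))),
               t(stats::setNames(f@r, paste0("r_", fn))))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFactorBank
#' @export
readFactorBank <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  fn <- suffFeatureNames()
  lapply(seq_len(nrow(df)), function(i)
    new("NormalizationFactors", subjectId = df$subject_id[i],
        m = stats::setNames(as.numeric(df[i, paste0("m_", fn)]), fn),
        r = stats::setNames(as.numeric(df[i, paste0("r_", fn)]), fn)))
}

#' Write a subject record to a directory of CSV files
#'
#' Waveform channels as per-channel `(time_s, value)` CSV, the beat series,
#' stage annotations, assessment times and (when present) the latent truth
#' as CSV tables.
#'
#' @param record a [SubjectRecord-class].
#' @param dir output directory (created if missing).
#' @export
writeSubjectRecord <- function(record, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- record@fs
  for (ch in names(record@channels)) {
    v <- record@channels[[ch]]
    write.csv(data.frame(time_s = (seq_along(v) - 1) / fs, value = v),
              file.path(dir, paste0(ch, ".csv")), row.names = FALSE)
  }
  write.csv(record@beatSeries, file.path(dir, "beats.csv"),
            row.names = FALSE)
  write.csv(record@stages, file.path(dir, "stages.csv"), row.names = FALSE)
  write.csv(data.frame(time_s = record@assessmentTimes),
            file.path(dir, "assessments.csv"), row.names = FALSE)
  if (length(record@truth))
    write.csv(record@truth$latent, file.path(dir, "truth_latent.csv"),
              row.names = FALSE)
  jsonlite::write_json(list(subject_id = record@subjectId, fs = fs),
                       file.path(dir, "record.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeSubjectRecord
#' @export
readSubjectRecord <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "record.json"))
  chans <- list()
  for (ch in c("ecg", "ppg", "ap", "svo2")) {
    f <- file.path(dir, paste0(ch, ".csv"))
    if (file.exists(f)) chans[[ch]] <- read.csv(f)$value
  }
  truthF <- file.path(dir, "truth_latent.csv")
  truth <- if (file.exists(truthF)) list(latent = read.csv(truthF)) else
    list()
  new("SubjectRecord", subjectId = man$subject_id, fs = man$fs,
      channels = chans,
      beatSeries = read.csv(file.path(dir, "beats.csv")),
      stages = read.csv(file.path(dir, "stages.csv")),
      assessmentTimes = read.csv(file.path(dir, "assessments.csv"))$time_s,
      truth = truth)
}

.CONFIG_KEYS <- c("nSubjects", "stableDuration", "waitingDuration",
                  "bleedMapStop", "bleedSensitivity", "bolusDuration",
                  "bolusResponse", "assessmentInterval",
                  "assessmentIntervalBolus", "maxAssessments",
                  "populationMeans", "populationSds", "subjectShiftSd",
                  "subjectScaleSd", "noiseSd", "obsNoiseSd",
                  "featureNoiseSd", "rrJitterSd", "respiratoryRate",
                  "waveformFs", "kSd", "segmentsPerStage", "seed")

#' Read a run configuration (YAML or JSON)
#'
#' Top-level keys `cohort` (any subset of the [cohortConfig()] arguments),
#' `oap` (K, seed, scorer hyperparameters) and `evaluation` (fpr0, fnr0,
#' costRatios) are recognized; unknown keys anywhere are rejected.
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return List with elements `cohort` (a [CohortConfig-class]), `oap`,
#'   `evaluation`.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), c("cohort", "oap", "evaluation"))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  ch <- raw$cohort
  if (!is.null(ch)) {
    bad <- setdiff(names(ch), .CONFIG_KEYS)
    if (length(bad))
      stop("unknown cohort keys: ", paste(bad, collapse = ", "))
    for (k in c("populationMeans", "populationSds", "segmentsPerStage"))
      if (!is.null(ch[[k]])) ch[[k]] <- unlist(ch[[k]])
  }
  oap <- raw$oap
  badO <- setdiff(names(oap), c("K", "seed", "numTrees", "maxDepth",
                                "minNodeSize", "mtry"))
  if (length(badO)) stop("unknown oap keys: ", paste(badO, collapse = ", "))
  ev <- raw$evaluation
  badE <- setdiff(names(ev), c("fpr0", "fnr0", "costRatios"))
  if (length(badE))
    stop("unknown evaluation keys: ", paste(badE, collapse = ", "))
  list(cohort = do.call(cohortConfig, as.list(ch)),
       oap = if (is.null(oap)) list() else oap,
       evaluation = if (is.null(ev)) list() else ev)
}
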