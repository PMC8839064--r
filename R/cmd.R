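## Pipeline commands backing the command-line interface
## (inst/cli/oapredict.R): simulate -> featurize -> evaluate.

.cfgHash <- function(config) {
  s <- paste(vapply(.CONFIG_KEYS, function(k)
    paste(format(methods::slot(config, k), digits = 15), collapse = ","),
    character(1)), collapse = ";")
  .stringHash(s)
}

#' Simulate a cohort to disk
#'
#' Writes one directory per subject (waveform channels, beat series, stage
#' annotations, truth) plus a manifest recording the seed, config hash and
#' feature-order hash.
#'
#' @param config a [CohortConfig-class].
#' @param outDir output directory, created if missing.
#' @return The manifest, invisibly.
#' @export
cmdSimulate <- function(config, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  recs <- simulateCohort(config)
  for (r in recs) writeSubjectRecord(r, file.path(outDir, r@subjectId))
  manifest <- list(n_subjects = config@nSubjects, seed = config@seed,
                   config_hash = .cfgHash(config),
                   feature_order_hash = featureOrderHash(),
                   subjects = as.list(names(recs)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  message("simulated ", length(recs), " subjects into ", outDir)
  invisible(manifest)
}

#' Featurize a simulated cohort directory
#'
#' @param inDir directory written by [cmdSimulate()].
#' @param outCsv feature CSV path.
#' @param segmentsPerStage,kSd passed to [sampleSegments()].
#' @return The [SuffFeatureSet-class], invisibly.
#' @export
cmdFeaturize <- function(inDir, outCsv,
                         segmentsPerStage = c(stable = 2L, bleeding = 1L,
                                              waiting = 1L),
                         kSd = 1) {
  man <- jsonlite::read_json(file.path(inDir, "manifest.json"))
  if (length(man$subjects) == 0L) stop("empty cohort")
  if (!identical(man$feature_order_hash, featureOrderHash()))
    stop("cohort was written under a different feature ordering")
  recs <- lapply(man$subjects, function(s)
    readSubjectRecord(file.path(inDir, s)))
  fset <- featurizeCohort(recs, segmentsPerStage, kSd)
  writeFeatureMatrix(fset, outCsv)
  message("featurized ", length(recs), " subjects: ", ncol(fset),
          " windows (", ncol(fset) / length(recs), " per subject) -> ",
          outCsv)
  invisible(fset)
}

#' Evaluate a feature matrix and write the report
#'
#' Runs the leave-one-subject-out protocol for the requested approaches and
#' writes the JSON report (per-subject AUROC, pooled metrics, cost-optimal
#' thresholds for each cost ratio, McNemar comparisons) plus a per-window
#' prediction CSV next to it.
#'
#' @param featuresCsv CSV written by [writeFeatureMatrix()].
#' @param reportJson output report path.
#' @param approach passed to [losoEvaluate()] (default "all").
#' @param K,seed,fpr0,fnr0,costRatios evaluation options.
#' @param ... passed to [trainScorer()].
#' @return The report list, invisibly.
#' @export
cmdEvaluate <- function(featuresCsv, reportJson, approach = "all",
                        K = 50L, seed = 1L, fpr0 = 0.030, fnr0 = 0.023,
                        costRatios = c(1 / 3, 1, 3), ...) {
  fset <- readFeatureMatrix(featuresCsv)
  if (length(subjectIds(fset)) < 3L) stop("need at least 3 subjects")
  res <- losoEvaluate(fset, approach = approach, K = K, seed = seed, ...)
  report <- evaluationReport(res, fpr0 = fpr0, fnr0 = fnr0,
                             costRatios = costRatios)
  report$seed <- seed
  report$feature_order_hash <- featureOrderHash()
  for (r in names(report$cost_analysis))   # ROC point lists only, keep JSON flat
    report$cost_analysis[[r]]$points <-
      lapply(report$cost_analysis[[r]]$points, function(p)
        p[c("fpr", "tpr", "threshold")])
  jsonlite::write_json(report, reportJson, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  predCsv <- sub("\\.json$", "_predictions.csv", reportJson)
  write.csv(as.data.frame(res), predCsv, row.names = FALSE)
  message("report -> ", reportJson)
  invisible(report)
}
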