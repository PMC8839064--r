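# LOSO protocol bookkeeping, reports, file round-trips, run configuration.

test_that("LOSO evaluates held-out resuscitation windows with full banks", {
  fs <- featureCohort(nSubjects = 5, seed = 91)
  res <- losoEvaluate(fs, "all", K = 25, seed = 91)
  d <- as.data.frame(res)
  folds <- S4Vectors::metadata(res)$folds
  expect_length(folds, 5)
  expect_true(all(vapply(folds, `[[`, numeric(1), "nTrainSubjects") == 4))
  expect_true(all(vapply(folds, `[[`, numeric(1), "bankSize") == 4))
  info <- windowInfo(fs)
  for (sid in subjectIds(fs)) {
    nRes <- sum(info$subject_id == sid & info$stage == "resuscitation")
    expect_equal(sum(d$subject_id == sid & d$approach == "oap"), nRes)
  }
  expect_setequal(unique(d$approach), c("without", "with", "oap"))
  # determinism of the full protocol
  res2 <- losoEvaluate(fs, "all", K = 25, seed = 91)
  expect_identical(as.data.frame(res2), d)
})

test_that("subjects without resuscitation windows are skipped with warning", {
  fs <- featureCohort(nSubjects = 5, seed = 13)
  keep <- !(windowInfo(fs)$subject_id == "S02" &
              windowInfo(fs)$stage == "resuscitation")
  fs2 <- fs[, keep]
  expect_warning(res <- losoEvaluate(fs2, "without", seed = 13), "S02")
  expect_length(S4Vectors::metadata(res)$folds, 4)
})

test_that("an identical twin of a training subject is perfectly ranked
           under its own baseline when the cohort is separable", {
  # construct a cohort where the normalized class-conditionals are disjoint
  set.seed(6)
  mkSubj <- function(sid, shift, scale) {
    nWin <- 11
    stage <- rep(c("stable", "bleeding", "resuscitation"), c(3, 2, 3))
    sev <- c(0, 0, 0, 1, 1, 1, 0.5, 0)        # resuscitation recovers
    nSeg <- length(sev)
    lab <- ifelse(rep(sev, each = nWin) > 0.4, "insufficient", "sufficient")
    z <- matrix(rnorm(nSeg * nWin * 42, 0, 0.05), nSeg * nWin, 42)
    z[, 1] <- z[, 1] + 5 * rep(sev, each = nWin)
    x <- z * scale + shift
    colnames(x) <- suffFeatureNames()
    info <- data.frame(subject_id = sid,
                       segment_id = rep(paste0(sid, "_", seq_len(nSeg)),
                                        each = nWin),
                       window_index = rep(1:nWin, nSeg),
                       stage = rep(stage, each = nWin), label = lab,
                       t_start_s = seq_len(nSeg * nWin) * 10)
    SuffFeatureSet(x, info)
  }
  sets <- c(lapply(1:4, function(i) mkSubj(sprintf("A%d", i),
                                           shift = rnorm(1, 0, 2),
                                           scale = exp(rnorm(1, 0, 0.3)))),
            list(mkSubj("T1", shift = 1.4, scale = 0.7)))
  fs <- new("SuffFeatureSet", do.call(SummarizedExperiment::cbind, sets))
  res <- losoEvaluate(fs, "with", seed = 3)
  d <- as.data.frame(res)
  dT <- d[d$subject_id == "T1", ]
  expect_equal(auroc(rocCurve(dT$score, dT$label)), 1.0)
})

test_that("evaluation report carries three approaches and cost settings", {
  fs <- featureCohort(nSubjects = 5, seed = 29)
  res <- losoEvaluate(fs, "all", K = 25, seed = 29)
  rep <- evaluationReport(res)
  expect_setequal(names(rep$approaches), c("without", "with", "oap"))
  expect_length(rep$cost_analysis, 3)
  for (entry in rep$cost_analysis) {
    expect_setequal(names(entry$points), c("without", "with", "oap"))
    expect_true(entry$mcnemar$oap_vs_without >= 0 &&
                  entry$mcnemar$oap_vs_without <= 1)
  }
  for (ap in names(rep$approaches)) {
    expect_true(rep$approaches[[ap]]$auroc_mean >= 0 &&
                  rep$approaches[[ap]]$auroc_mean <= 1)
    expect_gte(rep$approaches[[ap]]$auroc_se, 0)
  }
})

test_that("feature matrices, factor banks and records round-trip via CSV", {
  fs <- featureCohort(nSubjects = 3, seed = 61)
  tmp <- tempfile(fileext = ".csv")
  writeFeatureMatrix(fs, tmp)
  fs2 <- readFeatureMatrix(tmp)
  expect_equal(featureValues(fs2), featureValues(fs), tolerance = 1e-12)
  expect_identical(windowInfo(fs2)$label, windowInfo(fs)$label)
  bank <- lapply(subjectIds(fs), function(s) fitNormalizationFactors(fs, s))
  tmpB <- tempfile(fileext = ".csv")
  writeFactorBank(bank, tmpB)
  bank2 <- readFactorBank(tmpB)
  expect_equal(nfMedians(bank2[[2]]), nfMedians(bank[[2]]),
               tolerance = 1e-12)
  expect_equal(nfRanges(bank2[[2]]), nfRanges(bank[[2]]), tolerance = 1e-12)
  rec <- cachedRecord()
  dir <- tempfile()
  writeSubjectRecord(rec, dir)
  rec2 <- readSubjectRecord(dir)
  expect_equal(rec2@channels$ecg, rec@channels$ecg, tolerance = 1e-6)
  expect_equal(rec2@stages$end, rec@stages$end)
  expect_equal(rec2@assessmentTimes, rec@assessmentTimes)
})

test_that("run configuration validates keys and builds a cohort config", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("cohort:", "  nSubjects: 4", "  seed: 9",
               "oap:", "  K: 20", "evaluation:", "  fpr0: 0.05"), tmp)
  cfg <- readRunConfig(tmp)
  expect_equal(cfg$cohort@nSubjects, 4L)
  expect_equal(cfg$oap$K, 20)
  writeLines(c("cohort:", "  nSubjects: 4", "bogus: 1"), tmp)
  expect_error(readRunConfig(tmp), "unknown")
  writeLines(c("cohort:", "  wrongKey: 4"), tmp)
  expect_error(readRunConfig(tmp), "unknown cohort")
})

test_that("simulate/featurize/evaluate commands chain on a tiny cohort", {
  outDir <- tempfile()
  cfg <- shortWaveConfig(seed = 3)
  man <- suppressMessages(cmdSimulate(cfg, outDir))
  expect_length(man$subjects, 2)
  expect_true(file.exists(file.path(outDir, "S01", "ecg.csv")))
  featCsv <- file.path(outDir, "features.csv")
  fset <- suppressWarnings(suppressMessages(cmdFeaturize(outDir, featCsv)))
  expect_true(file.exists(featCsv))
  expect_equal(nrow(readFeatureMatrix(featCsv)), 42)
  # evaluate needs >= 3 subjects
  expect_error(cmdEvaluate(featCsv, tempfile(fileext = ".json")),
               "3 subjects")
})
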