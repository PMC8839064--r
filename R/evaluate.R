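## Nested leave-one-subject-out evaluation of the three approaches:
##   without -- raw features on both sides (no baseline anywhere),
##   with    -- self-normalized training AND test data (test baseline known),
##   oap     -- self-normalized training, majority-vote fractions for the
##              baseline-less test subject.

#' Leave-one-subject-out evaluation
#'
#' For each fold the scorer is trained on all other subjects' windows from
#' all stages and evaluated on the held-out subject's resuscitation windows
#' only, mirroring deployment during resuscitation.  Folds whose held-out
#' subject has no resuscitation windows are skipped with a warning.  With
#' `approach = "all"` the three approaches share each fold's training data
#' (and the self-normalized scorer is shared between "with" and the final
#' OAP scorer, which are trained on identical data and seed).
#'
#' @param fset a cohort [SuffFeatureSet-class] (>= 3 subjects).
#' @param approach one of "without", "with", "oap", "all".
#' @param K OAP candidate-pool size.
#' @param seed integer; fold f uses `seed + f` for its scorers.
#' @param ... passed to [trainScorer()].
#' @return An [S4Vectors::DataFrame] with one row per (approach, test
#'   window): subject_id, approach, score, label, segment_id, window_index.
#'   `metadata()$folds` records per-fold training-subject and vote-bank
#'   sizes and the selected OAP threshold.
#' @export
losoEvaluate <- function(fset, approach = c("without", "with", "oap", "all"),
                         K = 50L, seed = 1L, ...) {
  approach <- match.arg(approach)
  wanted <- if (approach == "all") c("without", "with", "oap") else approach
  info <- windowInfo(fset)
  subj <- .prepareSubjects(fset)
  if (length(subj) < 3L) stop("need at least 3 subjects")
  if (!any(info$stage == "resuscitation"))
    stop("no resuscitation windows to evaluate on")

  rows <- list(); folds <- list()
  for (f in seq_along(subj)) {
    held <- subj[[f]]
    if (length(held$resIdx) == 0L) {
      warning("subject ", held$id,
              " has no resuscitation windows; fold skipped")
      next
    }
    foldSeed <- seed + f
    train <- subj[-f]
    yTr <- unlist(lapply(train, `[[`, "labels"))
    testRaw <- held$raw[held$resIdx, , drop = FALSE]
    testLab <- held$labels[held$resIdx]
    fold <- list(subject = held$id, nTrainSubjects = length(train))

    scores <- list()
    if ("without" %in% wanted) {
      sc <- trainScorer(do.call(rbind, lapply(train, `[[`, "raw")), yTr,
                        seed = foldSeed, ...)
      scores$without <- scoreWindows(sc, testRaw)
    }
    if (any(c("with", "oap") %in% wanted)) {
      scSelf <- trainScorer(do.call(rbind, lapply(train, `[[`, "selfNorm")),
                            yTr, seed = foldSeed, ...)
      if ("with" %in% wanted)
        scores$with <- scoreWindows(scSelf,
                                    held$selfNorm[held$resIdx, ,
                                                  drop = FALSE])
      if ("oap" %in% wanted) {
        if (approach == "oap") {
          pred <- fitOAP(fset[, info$subject_id != held$id], K = K,
                         seed = foldSeed, ...)
        } else {
          search <- selectThreshold(fset[, info$subject_id != held$id],
                                    K = K, seed = foldSeed, ...)
          pred <- new("OAPredictor", scorer = scSelf,
                      factorBank = lapply(train, `[[`, "factors"),
                      tauStar = search@tauStar, search = search,
                      searchK = as.integer(K), seed = as.integer(foldSeed))
        }
        scores$oap <- predictOAP(pred, testRaw)
        fold$bankSize <- length(pred@factorBank)
        fold$tauStar <- pred@tauStar
      }
    }
    heldInfo <- info[info$subject_id == held$id, ][held$resIdx, ]
    for (ap in names(scores))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = held$id, approach = ap, score = scores[[ap]],
        label = testLab, segment_id = heldInfo$segment_id,
        window_index = heldInfo$window_index)
    folds[[length(folds) + 1L]] <- fold
  }
  if (length(rows) == 0L) stop("no evaluable folds")
  out <- DataFrame(do.call(rbind, rows))
  metadata(out)$folds <- folds
  metadata(out)$seed <- seed
  out
}

## per-subject ROC curves for one approach; subjects whose resuscitation
## windows hold a single class cannot contribute a curve
.subjectCurves <- function(res, ap) {
  d <- as.data.frame(res[res$approach == ap, ])
  out <- list()
  for (sid in unique(d$subject_id)) {
    ds <- d[d$subject_id == sid, ]
    if (length(unique(ds$label)) < 2L) next
    out[[sid]] <- rocCurve(ds$score, ds$label)
  }
  out
}

#' Summarize a LOSO evaluation into the standard report
#'
#' Per-approach: mean and standard error of the per-subject AUROC, mean
#' per-subject TPR at a bounded FPR and TNR at a bounded FNR, and the pooled
#' (windows concatenated across test subjects) ROC.  Cost analysis: for each
#' C_FP/C_FN ratio, the iso-performance slope uses the mean per-subject
#' negative-to-positive window ratio; the cost-optimal threshold is selected
#' on each approach's pooled curve, predictions are binarized there, and the
#' approaches are compared by McNemar tests on the concatenated windows.
#'
#' @param res result of [losoEvaluate()] (run with `approach = "all"` for
#'   the full report).
#' @param fpr0,fnr0 low-error evaluation points (defaults 0.030 / 0.023).
#' @param costRatios C_FP/C_FN settings, default `c(1/3, 1, 3)`.
#' @return Nested list, JSON-ready.
#' @export
evaluationReport <- function(res, fpr0 = 0.030, fnr0 = 0.023,
                             costRatios = c(1 / 3, 1, 3)) {
  d <- as.data.frame(res)
  approaches <- unique(d$approach)
  perSubj <- list(); pooled <- list()
  for (ap in approaches) {
    curves <- .subjectCurves(res, ap)
    aucs <- vapply(curves, auroc, numeric(1))
    da <- d[d$approach == ap, ]
    pooledCurve <- rocCurve(da$score, da$label)
    perSubj[[ap]] <- list(
      n_subjects = length(curves),
      auroc_mean = mean(aucs),
      auroc_se = if (length(aucs) > 1) sd(aucs) / sqrt(length(aucs)) else NA,
      auroc_by_subject = as.list(aucs),
      tpr_at_fpr = mean(vapply(curves, tprAtFpr, numeric(1), fpr0 = fpr0)),
      tnr_at_fnr = mean(vapply(curves, tnrAtFnr, numeric(1), fnr0 = fnr0)))
    pooled[[ap]] <- list(curve = pooledCurve,
                         auroc = auroc(pooledCurve),
                         scores = da$score, labels = da$label)
  }

  ## class frequencies: mean per-subject insufficient/sufficient ratio
  ratios <- vapply(split(d[d$approach == approaches[1], ],
                         d[d$approach == approaches[1], "subject_id"]),
                   function(ds) {
                     p <- sum(ds$label == "sufficient")
                     n <- sum(ds$label == "insufficient")
                     if (p > 0) n / p else NA_real_
                   }, numeric(1))
  npRatio <- mean(ratios, na.rm = TRUE)

  cost <- list()
  for (ratio in costRatios) {
    spec <- costSpec(p = 1, n = npRatio, cFP = ratio, cFN = 1)
    slope <- isoSlope(spec)
    entry <- list(cfp_cfn = ratio, slope = slope, points = list(),
                  mcnemar = list())
    binPred <- list()
    for (ap in approaches) {
      pt <- costOptimalPoint(pooled[[ap]]$curve, slope)
      entry$points[[ap]] <- pt
      binPred[[ap]] <- as.integer(pooled[[ap]]$scores >= pt$threshold)
    }
    labs <- pooled[[approaches[1]]]$labels
    if (all(c("oap", "without") %in% approaches))
      entry$mcnemar$oap_vs_without <- mcnemarTest(
        buildContingency(binPred$oap, binPred$without, labs))
    if (all(c("oap", "with") %in% approaches))
      entry$mcnemar$oap_vs_with <- mcnemarTest(
        buildContingency(binPred$oap, binPred$with, labs))
    cost[[sprintf("ratio_%g", ratio)]] <- entry
  }

  list(approaches = perSubj,
       pooled_auroc = lapply(pooled, `[[`, "auroc"),
       np_ratio = npRatio,
       cost_analysis = cost,
       folds = metadata(res)$folds)
}
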