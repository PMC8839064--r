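## The Optimized Aggregation of Predictions framework: train on
## self-normalized data, pick the binarization threshold that makes the
## training-baseline majority vote mimic the (unavailable at deployment)
## self-normalized predictions, and predict for new subjects as a positive
## vote fraction over the bank of training-subject normalization factors.

## Per-subject views of a cohort feature set, computed once per fit/fold.
.prepareSubjects <- function(fset) {
  info <- windowInfo(fset)
  x <- featureValues(fset)
  ids <- unique(info$subject_id)
  out <- lapply(ids, function(sid) {
    sel <- info$subject_id == sid
    xs <- x[sel, , drop = FALSE]
    factors <- fitNormalizationFactors(
      xs[info$stage[sel] == "stable", , drop = FALSE], subject = sid)
    list(id = sid, raw = xs, labels = info$label[sel],
         stage = info$stage[sel],
         resIdx = which(info$stage[sel] == "resuscitation"),
         factors = factors,
         selfNorm = applyNormalization(xs, factors))
  })
  names(out) <- ids
  out
}

#' Candidate binarization thresholds
#'
#' Uniformly samples (by rank, endpoints included) at most `K` candidates
#' from the unique prediction scores observed on validation data; all unique
#' scores are returned when there are no more than `K` of them.
#'
#' @param validationScores numeric scores.
#' @param K maximum number of candidates, default 50.
#' @return Sorted numeric vector of candidate thresholds.
#' @export
#' @examples
#' candidateThresholds(c(0.2, 0.8, 0.2, 0.5), K = 50)
candidateThresholds <- function(validationScores, K = 50L) {
  u <- sort(unique(validationScores[is.finite(validationScores)]))
  if (length(u) == 0L) stop("no scores to draw candidate thresholds from")
  if (length(u) <= K) return(u)
  u[unique(round(seq(1, length(u), length.out = K)))]
}

## score raw rows under every bank entry in one forest call
.voteScores <- function(scorer, rawRows, bank) {
  B <- length(bank)
  stacked <- do.call(rbind, lapply(bank, function(f)
    applyNormalization(rawRows, f)))
  s <- scoreWindows(scorer, stacked)
  matrix(s, nrow = nrow(rawRows), ncol = B)
}

#' Majority-vote prediction under a bank of baselines
#'
#' Normalizes the raw rows with each bank entry, scores each version,
#' binarizes at `tau` (scores >= tau are positive) and returns, per row, the
#' fraction of positive votes -- interpretable as how many previously seen
#' subjects vote for "sufficient".
#'
#' @param scorer a [ScorerModel-class].
#' @param rawRows windows-by-features matrix of un-normalized data.
#' @param bank non-empty list of [NormalizationFactors-class].
#' @param tau binarization threshold.
#' @return Vote fractions in \[0, 1\], one per row.
#' @export
votePredict <- function(scorer, rawRows, bank, tau) {
  if (length(bank) == 0L) stop("empty factor bank")
  s <- .voteScores(scorer, rawRows, bank)
  rowMeans(s >= tau)
}

.corrObj <- function(predStar, voteFracs) {
  if (sd(predStar) == 0 || sd(voteFracs) == 0)
    return(list(value = 0, degenerate = TRUE))
  list(value = cor(predStar, voteFracs), degenerate = FALSE)
}

#' Correlation objective of the threshold search
#'
#' Pearson correlation between the self-normalized validation predictions
#' (Prediction*) and the majority-vote fractions.  A degenerate input with
#' zero variance contributes 0 to the objective, with a warning.
#'
#' @param predStar continuous scores on self-normalized validation rows.
#' @param voteFracs vote fractions on the same rows.
#' @return Numeric scalar in \[-1, 1\].
#' @export
correlationObjective <- function(predStar, voteFracs) {
  if (length(predStar) != length(voteFracs))
    stop("predStar and voteFracs must have equal length")
  if (length(predStar) < 2L) stop("need at least 2 windows")
  r <- .corrObj(predStar, voteFracs)
  if (r$degenerate)
    warning("zero-variance input; objective contribution set to 0")
  r$value
}

#' Select the binarization threshold by inner leave-one-subject-out search
#'
#' For each inner fold, the scorer is retrained on the remaining subjects'
#' self-normalized windows (all stages); the held-out validation subject's
#' resuscitation windows are scored both under its own factors (Prediction*)
#' and under every inner-training subject's factors (the vote bank).
#' Candidates are drawn per fold from the fold's unique vote scores and
#' pooled into a union grid; the selected threshold maximizes the mean
#' Pearson correlation between Prediction* and the vote fraction across
#' folds, ties broken toward the smallest threshold.
#'
#' @param fset a [SuffFeatureSet-class] of the training subjects (>= 3).
#' @param K candidate-pool size per fold, default 50.
#' @param seed integer; inner-fold scorers use `seed + fold index`.
#' @param ... passed to [trainScorer()].
#' @return A [ThresholdSearch-class].
#' @export
selectThreshold <- function(fset, K = 50L, seed = 1L, ...) {
  subj <- .prepareSubjects(fset)
  if (length(subj) < 3L) stop("need at least 3 training subjects")
  folds <- list()
  for (v in seq_along(subj)) {
    val <- subj[[v]]
    if (length(val$resIdx) == 0L) {
      warning("validation subject ", val$id,
              " has no resuscitation windows; inner fold skipped")
      next
    }
    train <- subj[-v]
    xTr <- do.call(rbind, lapply(train, `[[`, "selfNorm"))
    yTr <- unlist(lapply(train, `[[`, "labels"))
    scorer <- trainScorer(xTr, yTr, seed = seed + v, ...)
    predStar <- scoreWindows(scorer,
                             val$selfNorm[val$resIdx, , drop = FALSE])
    S <- .voteScores(scorer, val$raw[val$resIdx, , drop = FALSE],
                     lapply(train, `[[`, "factors"))
    folds[[length(folds) + 1L]] <-
      list(predStar = predStar, S = S,
           candidates = candidateThresholds(as.vector(S), K))
  }
  if (length(folds) == 0L)
    stop("no usable inner folds: no validation subject has resuscitation windows")
  grid <- sort(unique(unlist(lapply(folds, `[[`, "candidates"))))
  degenerate <- TRUE
  meanCorr <- vapply(grid, function(tau) {
    contrib <- vapply(folds, function(f) {
      r <- .corrObj(f$predStar, rowMeans(f$S >= tau))
      if (!r$degenerate) degenerate <<- FALSE
      r$value
    }, numeric(1))
    mean(contrib)
  }, numeric(1))
  if (degenerate)
    stop("threshold search degenerate: all correlation objectives undefined")
  best <- which(meanCorr >= max(meanCorr) - 1e-12)[1]
  new("ThresholdSearch", candidates = grid, meanCorrelation = meanCorr,
      tauStar = grid[best])
}

setMethod("show", "ThresholdSearch", function(object) {
  cat("ThresholdSearch:", length(object@candidates), "candidates, tau* =",
      format(object@tauStar, digits = 4), "(mean corr",
      format(max(object@meanCorrelation), digits = 4), ")\n")
})

#' Fit the Optimized Aggregation of Predictions predictor
#'
#' Runs [selectThreshold()] on the training subjects, then retrains the final
#' scorer on all training subjects' self-normalized windows (all stages) and
#' stores every training subject's normalization factors as the vote bank.
#'
#' @param fset a [SuffFeatureSet-class] of the training subjects (>= 3).
#' @param K candidate-pool size, default 50.
#' @param seed integer seed controlling the whole fit.
#' @param ... passed to [trainScorer()].
#' @return An [OAPredictor-class].
#' @export
fitOAP <- function(fset, K = 50L, seed = 1L, ...) {
  subj <- .prepareSubjects(fset)
  if (length(subj) < 3L) stop("need at least 3 training subjects")
  search <- selectThreshold(fset, K = K, seed = seed, ...)
  xTr <- do.call(rbind, lapply(subj, `[[`, "selfNorm"))
  yTr <- unlist(lapply(subj, `[[`, "labels"))
  scorer <- trainScorer(xTr, yTr, seed = seed, ...)
  new("OAPredictor", scorer = scorer,
      factorBank = lapply(subj, `[[`, "factors"),
      tauStar = search@tauStar, search = search,
      searchK = as.integer(K), seed = as.integer(seed))
}

#' Predict vote fractions for a baseline-less subject
#'
#' @param predictor an [OAPredictor-class].
#' @param rawRows windows-by-features matrix of raw (un-normalized) data.
#' @return Vote fractions in \[0, 1\]; with a bank of B baselines the values
#'   lie on the grid 0, 1/B, ..., 1.
#' @export
predictOAP <- function(predictor, rawRows) {
  if (!identical(colnames(rawRows), predictor@scorer@featureNames))
    stop("feature columns do not match the fitted predictor")
  votePredict(predictor@scorer, rawRows, predictor@factorBank,
              predictor@tauStar)
}
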