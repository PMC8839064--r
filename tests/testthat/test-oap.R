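# Scorer contract, threshold machinery, vote aggregation, OAP fit/predict.

.sepData <- function(n = 120, seed = 1) {
  set.seed(seed)
  y <- rep(c("insufficient", "sufficient"), each = n / 2)
  x <- matrix(rnorm(n * 42, 0, 0.3), n, 42)
  x[, 1] <- x[, 1] + 3 * (y == "sufficient")   # cleanly separable in x1
  colnames(x) <- suffFeatureNames()
  list(x = x, y = y)
}

test_that("scorer separates separable data and is seed-deterministic", {
  d <- .sepData()
  sc <- trainScorer(d$x, d$y, seed = 5)
  s <- scoreWindows(sc, d$x)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(auroc(rocCurve(s, d$y)), 1.0)
  sc2 <- trainScorer(d$x, d$y, seed = 5)
  expect_identical(scoreWindows(sc2, d$x), s)
  expect_error(trainScorer(d$x, rep("sufficient", nrow(d$x))),
               "both classes")
})

test_that("permuted labels score at chance level", {
  set.seed(8)
  n <- 300
  x <- matrix(rnorm(n * 42), n, 42); colnames(x) <- suffFeatureNames()
  y <- sample(rep(c("insufficient", "sufficient"), each = n / 2))
  half <- seq_len(n / 2)
  sc <- trainScorer(x[half, ], y[half], seed = 2)
  a <- auroc(rocCurve(scoreWindows(sc, x[-half, ]), y[-half]))
  expect_lt(abs(a - 0.5), 0.1)
})

test_that("missing features are imputed with training medians", {
  d <- .sepData()
  xm <- d$x
  xm[3, 1] <- NA; xm[5, 10] <- NA
  sc <- trainScorer(xm, d$y, seed = 3)
  s <- scoreWindows(sc, xm)
  expect_true(all(is.finite(s)))
  expect_equal(sc@imputeMedians[[10]], median(xm[, 10], na.rm = TRUE))
})

test_that("candidate thresholds sample unique scores uniformly by rank", {
  expect_equal(candidateThresholds(c(0.2, 0.8, 0.2, 0.5, 0.9, 0.1)),
               c(0.1, 0.2, 0.5, 0.8, 0.9))
  expect_equal(candidateThresholds(rep(0.4, 10)), 0.4)
  u <- seq(0.005, 1, by = 0.005)[1:100]
  got <- candidateThresholds(sample(u), K = 10)
  expect_equal(match(got, sort(u)), c(1, 12, 23, 34, 45, 56, 67, 78, 89, 100))
  expect_error(candidateThresholds(numeric(0)), "no scores")
})

test_that("vote fractions are exact positive-vote percentages", {
  d <- .sepData()
  sc <- trainScorer(d$x, d$y, seed = 1)
  mkF <- function(m, r) new("NormalizationFactors", subjectId = "v",
                            m = stats::setNames(rep(m, 42), suffFeatureNames()),
                            r = stats::setNames(rep(r, 42), suffFeatureNames()))
  bank <- lapply(seq(-0.2, 0.2, length.out = 15), function(m) mkF(m, 1))
  v <- votePredict(sc, d$x, bank, tau = 0.5)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(abs(v * 15 - round(v * 15)) < 1e-9))  # 15-voter grid
  # tau = 0: every score >= 0 is a positive vote
  expect_equal(votePredict(sc, d$x, bank, tau = 0), rep(1, nrow(d$x)))
  # identical factors vote unanimously
  same <- lapply(1:7, function(i) mkF(0, 1))
  vs <- votePredict(sc, d$x, same, tau = 0.5)
  expect_true(all(vs %in% c(0, 1)))
  # voter order is irrelevant; fraction equals mean of per-voter votes
  vPerm <- votePredict(sc, d$x, rev(bank), tau = 0.5)
  expect_equal(vPerm, v)
  expect_error(votePredict(sc, d$x, list(), 0.5), "empty")
})

test_that("correlation objective handles perfect, reversed and degenerate
           inputs", {
  p <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(correlationObjective(p, p), 1.0)
  expect_equal(correlationObjective(p, 1 - p), -1.0)
  expect_warning(z <- correlationObjective(p, rep(0.4, 4)), "zero-variance")
  expect_equal(z, 0)
  expect_error(correlationObjective(p, p[-1]), "equal length")
})

test_that("threshold search maximizes mean correlation deterministically", {
  fs <- featureCohort(nSubjects = 5, seed = 31)
  ts1 <- selectThreshold(fs, K = 25, seed = 31)
  ts2 <- selectThreshold(fs, K = 25, seed = 31)
  expect_identical(ts1@tauStar, ts2@tauStar)
  expect_identical(ts1@meanCorrelation, ts2@meanCorrelation)
  best <- max(ts1@meanCorrelation)
  expect_equal(ts1@meanCorrelation[ts1@candidates == ts1@tauStar][1], best)
  # smallest tau wins among (near-)ties
  atMax <- ts1@candidates[ts1@meanCorrelation >= best - 1e-12]
  expect_equal(ts1@tauStar, min(atMax))
  expect_error(selectThreshold(fs[, windowInfo(fs)$subject_id %in%
                                      subjectIds(fs)[1:2]]), "3 training")
})

test_that("OAP fit wires the bank, threshold and final scorer together", {
  fs <- featureCohort(nSubjects = 5, seed = 47)
  pred <- fitOAP(fs, K = 25, seed = 47)
  expect_s4_class(pred, "OAPredictor")
  expect_length(factorBank(pred), 5)
  expect_identical(names(factorBank(pred)), as.character(subjectIds(fs)))
  expect_true(tauStar(pred) >= 0 && tauStar(pred) <= 1)
  info <- windowInfo(fs)
  raw <- featureValues(fs)[info$stage == "resuscitation", , drop = FALSE][1:20, ]
  v <- predictOAP(pred, raw)
  expect_true(all(abs(v * 5 - round(v * 5)) < 1e-9))  # 5-voter grid
  # duplicated rows predict identically; fit is a pure function of its seed
  expect_identical(predictOAP(pred, raw[c(1, 1), ]),
                   rep(predictOAP(pred, raw[1, , drop = FALSE]), 2))
  pred2 <- fitOAP(fs, K = 25, seed = 47)
  expect_identical(tauStar(pred2), tauStar(pred))
  expect_identical(predictOAP(pred2, raw), v)
  bad <- raw; colnames(bad) <- rev(colnames(raw))
  expect_error(predictOAP(pred, bad), "match")
})

test_that("zero-heterogeneity cohorts collapse votes toward unanimity", {
  fs <- generateFeatureCohort(cohortConfig(nSubjects = 5, seed = 15,
                                           subjectShiftSd = 0,
                                           subjectScaleSd = 0))
  pred <- fitOAP(fs, K = 25, seed = 15)
  info <- windowInfo(fs)
  raw <- featureValues(fs)[info$stage == "resuscitation", , drop = FALSE]
  v <- predictOAP(pred, raw)
  # votes concentrate at unanimity when baselines coincide up to sampling
  # noise in the stable-stage factor estimates
  expect_gt(mean(v %in% c(0, 1)), 0.6)
  expect_lt(mean(pmin(v, 1 - v)), 0.15)
})
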