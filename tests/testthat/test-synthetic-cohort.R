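# Simulator: subject parameters, latent dynamics, waveform construction,
# feature-level tier.

test_that("subject parameters follow the stated dispersions", {
  cfg <- cohortConfig(subjectShiftSd = 0, subjectScaleSd = 0)
  set.seed(1)
  p <- drawSubjectParams(cfg)
  expect_true(all(p@shifts == 0))
  expect_true(all(p@scales == 1))
  # determinism under a fixed seed
  set.seed(99); p1 <- drawSubjectParams(cohortConfig())
  set.seed(99); p2 <- drawSubjectParams(cohortConfig())
  expect_identical(p1, p2)
  # Monte-Carlo check of the log-scale dispersion
  cfg3 <- cohortConfig(subjectScaleSd = 0.3)
  set.seed(7)
  ls <- replicate(1000, log(drawSubjectParams(cfg3)@scales[["map"]]))
  expect_lt(abs(sd(ls) - 0.3) / 0.3, 0.1)
})

test_that("latent bleeding declines monotonically to the stop pressure", {
  cfg <- shortWaveConfig(seed = 3, noiseSd = 0)
  set.seed(31)
  params <- drawSubjectParams(cfg)
  sim <- simulateLatent(params, cfg)
  bl <- sim$latent[sim$latent$stage == "bleeding", ]
  expect_true(all(diff(bl$map) < 0))
  # ends at the first sample below 40 mmHg
  below <- which(bl$map < cfg@bleedMapStop)
  expect_equal(below, nrow(bl))
  expect_true(all(bl$map[-nrow(bl)] >= cfg@bleedMapStop))
  # stable stage spans the configured duration
  st <- sim$stages
  expect_equal(st$end[st$stage == "stable"] - st$start[st$stage == "stable"],
               cfg@stableDuration)
  # HR, PPV, SVV rise while MAP falls
  expect_gt(tail(bl$hr, 1), bl$hr[1])
  expect_gt(tail(bl$ppv, 1), bl$ppv[1])
})

test_that("default-protocol stable stage spans 1800 s", {
  cfg <- cohortConfig(seed = 8)
  set.seed(8)
  sim <- simulateLatent(drawSubjectParams(cfg), cfg)
  st <- sim$stages
  expect_equal(st$start[st$stage == "stable"], 0)
  expect_equal(st$end[st$stage == "stable"], 1800)
})

test_that("ineffective boluses leave every resuscitation assessment negative", {
  cfg <- shortWaveConfig(seed = 5)
  set.seed(51)
  params <- drawSubjectParams(cfg)
  params@bolusResponse <- 0
  sim <- simulateLatent(params, cfg)
  expect_true(all(sim$assessments$label == "insufficient"))
  badParams <- params; badParams@bleedSensitivity <- 0
  expect_error(simulateLatent(badParams, cfg), "terminate")
})

test_that("stage annotations are contiguous, ordered, with assessments in
           resuscitation", {
  recs <- simulateCohort(shortWaveConfig(seed = 19))
  for (rec in recs) {
    st <- rec@stages
    expect_identical(st$stage,
                     c("stable", "bleeding", "waiting", "resuscitation"))
    expect_equal(st$start[-1], st$end[-nrow(st)])
    res <- st[st$stage == "resuscitation", ]
    expect_true(all(rec@assessmentTimes > res$start &
                      rec@assessmentTimes <= res$end))
    expect_true(validObject(rec))
  }
})

test_that("constant-HR jitter-free synthesis gives exact R-R intervals", {
  rec <- cachedCleanRecord()   # homogeneous, noise-free, jitter-free
  stableBeats <- rec@truth$beatTimes[rec@truth$beatTimes < 150]
  rr <- diff(stableBeats)
  expect_lt(max(abs(rr - 60 / 90)), 1e-9)   # population HR 90, no hetero
  # R-peak count over 60 s matches the configured rate within one beat
  det <- detectRPeaks(rec@channels$ecg, rec@fs)
  expect_lt(abs(sum(det >= 60 & det < 120) - 90), 1 + 1e-9)
  # true PTT at baseline severity is the configured transit lag
  expect_equal(unique(round(rec@truth$ptt[rec@truth$beatTimes < 150], 6)),
               0.2)
})

test_that("cohort generation is reproducible and guards the LOSO minimum", {
  cfg <- cohortConfig(nSubjects = 16, seed = 64)
  expect_error(simulateCohort(cohortConfig(nSubjects = 1)), "2 subjects")
  expect_error(generateFeatureCohort(cohortConfig(nSubjects = 1)),
               "2 subjects")
  fs1 <- generateFeatureCohort(cfg)
  expect_length(subjectIds(fs1), 16)
  fs2 <- generateFeatureCohort(cohortConfig(nSubjects = 16, seed = 64))
  expect_identical(featureValues(fs1), featureValues(fs2))
  expect_identical(windowInfo(fs1), windowInfo(fs2))
})

test_that("feature tier: homogeneous cohorts share class-conditional means", {
  fs <- generateFeatureCohort(cohortConfig(nSubjects = 6, seed = 77,
                                           subjectShiftSd = 0,
                                           subjectScaleSd = 0))
  info <- windowInfo(fs)
  x <- featureValues(fs)
  sel <- info$stage == "stable"
  perSubj <- vapply(split(x[sel, "map_median"], info$subject_id[sel]),
                    mean, numeric(1))
  expect_lt(max(perSubj) - min(perSubj),
            6 * sd(x[sel, "map_median"]) / sqrt(sum(sel) / 6))
})

test_that("feature tier: self-normalized stable features center at zero", {
  fs <- featureCohort(nSubjects = 5, seed = 21)
  info <- windowInfo(fs)
  for (sid in subjectIds(fs)) {
    nf <- fitNormalizationFactors(fs, subject = sid)
    sel <- info$subject_id == sid & info$stage == "stable"
    z <- applyNormalization(featureValues(fs)[sel, , drop = FALSE], nf)
    expect_equal(unname(apply(z, 2, median)), rep(0, 42), tolerance = 1e-12)
  }
})

test_that("feature tier: inverse affine recovers the shared latent
           distribution", {
  cfg <- cohortConfig(nSubjects = 2, seed = 12,
                      segmentsPerStage = c(stable = 90L, bleeding = 1L,
                                           waiting = 1L))
  fs <- generateFeatureCohort(cfg)
  info <- windowInfo(fs)
  prm <- S4Vectors::metadata(fs)$subjectParams
  fm <- OAPredict:::.featureModel()
  inv <- function(sid, feat) {
    sel <- info$subject_id == sid & info$stage == "stable"
    x <- featureValues(fs)[sel, feat]
    (x - prm[[sid]]@shifts[[feat]] * fm[feat, "sd"]) / prm[[sid]]@scales[[feat]]
  }
  for (feat in c("map_median", "hr_median", "hrv_sdnn")) {
    ks <- suppressWarnings(stats::ks.test(inv("S01", feat), inv("S02", feat)))
    expect_lt(unname(ks$statistic), 0.1)   # ~1000 windows per subject
  }
})

test_that("label prevalence rises with recovery strength", {
  prev <- vapply(c(0.15, 0.34, 0.6), function(br) {
    fs <- generateFeatureCohort(cohortConfig(nSubjects = 8, seed = 55,
                                             bolusResponse = br))
    info <- windowInfo(fs)
    res <- info$stage == "resuscitation"
    mean(info$label[res] == "sufficient")
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})
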