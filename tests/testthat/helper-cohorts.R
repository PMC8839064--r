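# Shared fixtures, generated in code and cached per test run.  Waveform-tier
# configs shorten stage durations and the assessment cadence so one record
# simulates and featurizes in seconds; the latent dynamics, detectors and
# featurizer are identical to the default protocol.

shortWaveConfig <- function(seed = 7, ...) {
  cohortConfig(nSubjects = 2, stableDuration = 180, waitingDuration = 130,
               bleedSensitivity = 0.25, bolusResponse = 0.5,
               bolusDuration = 150, assessmentInterval = 180,
               assessmentIntervalBolus = 330, seed = seed, ...)
}

# simulate a single subject without paying for a whole cohort
simulateOneRecord <- function(cfg, subjectSeed = cfg@seed) {
  set.seed(subjectSeed)
  params <- drawSubjectParams(cfg, subjectId = "S01")
  synthesizeWaveforms(simulateLatent(params, cfg), params, cfg)
}

.cacheEnv <- new.env(parent = emptyenv())

# default short record (observation noise on)
cachedRecord <- function() {
  if (is.null(.cacheEnv$rec)) {
    .cacheEnv$rec <- simulateOneRecord(shortWaveConfig(seed = 7))
    .cacheEnv$beatData <- prepareBeatData(.cacheEnv$rec)
  }
  .cacheEnv$rec
}

cachedBeatData <- function() {
  cachedRecord()
  .cacheEnv$beatData
}

# deterministic record: no latent noise, no observation noise, no R-R jitter,
# homogeneous subject -- shared by the detector ground-truth tests
cachedCleanRecord <- function() {
  if (is.null(.cacheEnv$clean)) {
    .cacheEnv$clean <- simulateOneRecord(
      shortWaveConfig(seed = 23, noiseSd = 0, obsNoiseSd = 0,
                      rrJitterSd = 0, subjectShiftSd = 0,
                      subjectScaleSd = 0))
  }
  .cacheEnv$clean
}

featureCohort <- function(nSubjects = 6, seed = 42, ...) {
  generateFeatureCohort(cohortConfig(nSubjects = nSubjects, seed = seed, ...))
}

# nearest-neighbour distances from each x to the sorted reference times
nearestDist <- function(x, ref) {
  ref <- sort(ref)
  i <- findInterval(x, ref)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(ref))
  pmin(abs(x - ref[lo]), abs(x - ref[hi]))
}

# brute-force pairwise AUROC oracle: P(score_pos > score_neg) + 0.5 P(tie)
pairCountAuroc <- function(scores, labels) {
  pos <- scores[labels == 1 | labels == "sufficient"]
  neg <- scores[labels == 0 | labels == "insufficient"]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
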