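#' Build a cohort simulation configuration
#'
#' Defaults encode the laboratory protocol the simulator emulates: a 30-min
#' stabilization period, bleeding at constant rate until MAP first drops below
#' 40 mmHg, a 30-min waiting period, then fluid resuscitation with sufficiency
#' assessments every 5 min (11 min when a 6-min bolus was given) until the
#' subject's stable-period targets are re-crossed and confirmed at one further
#' assessment.  Population vital-sign levels are typical of anesthetized
#' swine.
#'
#' @param nSubjects number of subjects (default 16).
#' @param stableDuration,waitingDuration seconds (1800 each).
#' @param bleedMapStop mmHg (40).
#' @param bleedSensitivity latent MAP decline while bleeding, mmHg/s (0.05,
#'   i.e. roughly 15 min from baseline to 40 mmHg).
#' @param bolusDuration seconds per bolus (360).
#' @param bolusResponse latent severity restored per bolus, as a fraction of
#'   the stable-to-shock span (0.34: full recovery in about 3 boluses).
#' @param assessmentInterval,assessmentIntervalBolus seconds (300 / 660).
#' @param maxAssessments termination cap (12).
#' @param populationMeans,populationSds named numeric over
#'   c("map","hr","svo2","svv","ppv").
#' @param subjectShiftSd per-subject additive shift SD, in population-SD units
#'   (1.0).
#' @param subjectScaleSd SD of per-subject log scale factors (0.3).
#' @param noiseSd latent AR(1) noise as a fraction of the population SD (0.3).
#' @param obsNoiseSd additive waveform noise (0.02).
#' @param featureNoiseSd feature-tier within-class SD multiplier (1.0).
#' @param rrJitterSd fractional R-R jitter (0.01).
#' @param respiratoryRate Hz (0.25).
#' @param waveformFs Hz (250).
#' @param kSd sufficiency-target multiplier (1.0).
#' @param segmentsPerStage 2-min training segments sampled evenly per
#'   non-resuscitation stage.
#' @param seed master seed.
#' @return A validated [CohortConfig-class].
#' @export
#' @examples
#' cohortConfig(nSubjects = 4, seed = 7)
cohortConfig <- function(nSubjects = 16,
                         stableDuration = 1800,
                         waitingDuration = 1800,
                         bleedMapStop = 40,
                         bleedSensitivity = 0.05,
                         bolusDuration = 360,
                         bolusResponse = 0.34,
                         assessmentInterval = 300,
                         assessmentIntervalBolus = 660,
                         maxAssessments = 12,
                         populationMeans = c(map = 85, hr = 90, svo2 = 70,
                                             svv = 8, ppv = 9),
                         populationSds = c(map = 5, hr = 6, svo2 = 3,
                                           svv = 1.2, ppv = 1.2),
                         subjectShiftSd = 1.0,
                         subjectScaleSd = 0.3,
                         noiseSd = 0.3,
                         obsNoiseSd = 0.02,
                         featureNoiseSd = 1.0,
                         rrJitterSd = 0.01,
                         respiratoryRate = 0.25,
                         waveformFs = 250,
                         kSd = 1.0,
                         segmentsPerStage = c(stable = 2L, bleeding = 1L,
                                              waiting = 1L),
                         seed = 1L) {
  new("CohortConfig",
      nSubjects = as.integer(nSubjects),
      stableDuration = stableDuration,
      waitingDuration = waitingDuration,
      bleedMapStop = bleedMapStop,
      bleedSensitivity = bleedSensitivity,
      bolusDuration = bolusDuration,
      bolusResponse = bolusResponse,
      assessmentInterval = assessmentInterval,
      assessmentIntervalBolus = assessmentIntervalBolus,
      maxAssessments = as.integer(maxAssessments),
      populationMeans = populationMeans,
      populationSds = populationSds,
      subjectShiftSd = subjectShiftSd,
      subjectScaleSd = subjectScaleSd,
      noiseSd = noiseSd,
      obsNoiseSd = obsNoiseSd,
      featureNoiseSd = featureNoiseSd,
      rrJitterSd = rrJitterSd,
      respiratoryRate = respiratoryRate,
      waveformFs = waveformFs,
      kSd = kSd,
      segmentsPerStage = vapply(segmentsPerStage, as.integer, integer(1)),
      seed = as.integer(seed))
}
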