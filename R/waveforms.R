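## Stylized waveform synthesis.  Only the properties consumed downstream are
## modeled: R-peak timing (ECG), pulse foot/peak morphology and respiratory
## amplitude modulation (PPG), beat means (AP), and a slow SvO2 trend.

.PTT_BASE <- 0.20          # s, pulse transit at baseline
.PTT_GAIN <- 0.05          # s of added transit at full severity
.PPG_RISE <- 0.15          # s foot-to-peak

#' Synthesize waveform channels from a latent trajectory
#'
#' Generates ECG, PPG, arterial pressure and SvO2 channels at
#' `config@waveformFs` from the latent vitals.  Beats are placed by
#' integrating the latent heart rate with fractional R-R jitter
#' `config@rrJitterSd`; each ECG beat is a stylized R deflection (plus small
#' S and T waves).  Each PPG pulse starts at the beat time plus the latent
#' pulse-transit lag, rises to its peak over a fixed rise time and decays to
#' the next foot; pulse amplitudes are modulated at the respiratory rate with
#' a depth tracking the latent PPV, so PPV computed from the waveform follows
#' the latent PPV channel.  The device beat-to-beat series (MAP, SVV, PPV) is
#' sampled at the beat times, SVV as a scaled, noisier copy of PPV.  True
#' beat and foot times go into the record's `truth`.
#'
#' @param latentSim result of [simulateLatent()].
#' @param params a [SubjectParams-class].
#' @param config a [CohortConfig-class].
#' @return A [SubjectRecord-class].
#' @export
synthesizeWaveforms <- function(latentSim, params, config) {
  fs <- config@waveformFs
  if (fs < 100) stop("waveformFs too low to resolve the ECG template")
  lat <- latentSim$latent
  dur <- max(lat$time) + 1
  n <- round(dur * fs)
  tAxis <- (seq_len(n) - 1) / fs
  latAt <- function(col, t)
    approx(lat$time, lat[[col]], t, rule = 2)$y

  ## ---- beat times from latent HR ----
  beats <- numeric(ceiling(dur * 4))
  k <- 0L; t <- runif(1, 0, 0.5)
  while (t < dur - 0.2) {
    k <- k + 1L; beats[k] <- t
    rr <- 60 / latAt("hr", t)
    if (config@rrJitterSd > 0) rr <- rr * (1 + rnorm(1, 0, config@rrJitterSd))
    t <- t + max(rr, 0.25)
  }
  beats <- beats[seq_len(k)]
  sev <- pmin(1.1, pmax(0, latAt("severity", beats)))
  ptt <- .PTT_BASE + .PTT_GAIN * sev
  feet <- beats + ptt

  ## ---- ECG: R (narrow), S and T deflections per beat ----
  ## (subassignment kept inline so the channel vector is modified in place)
  ecg <- rnorm(n, 0, config@obsNoiseSd)
  deflections <- cbind(delay = c(0, 0.035, 0.25),
                       width = c(0.012, 0.012, 0.055),
                       amp = c(1.0, -0.22, 0.15))
  for (i in seq_along(beats)) {
    for (d in 1:3) {
      center <- beats[i] + deflections[d, "delay"]
      width <- deflections[d, "width"]
      i0 <- max(1L, floor((center - 3.5 * width) * fs) + 1L)
      i1 <- min(n, ceiling((center + 3.5 * width) * fs) + 1L)
      if (i1 < i0) next
      tt <- (seq.int(i0, i1) - 1) / fs
      ecg[i0:i1] <- ecg[i0:i1] + deflections[d, "amp"] *
        exp(-(tt - center)^2 / (2 * width^2))
    }
  }

  ## ---- PPG and AP, built beat by beat ----
  ppg <- rnorm(n, 0, config@obsNoiseSd)
  ap <- latAt("map", tAxis)
  ppvBeat <- latAt("ppv", beats)
  resp <- sin(2 * pi * config@respiratoryRate * beats)
  ampPpg <- (1 - 0.4 * sev) * (1 + (ppvBeat / 100) / 2 * resp)
  pp <- 40 * (1 - 0.45 * sev) * (1 + (ppvBeat / 100) / 2 * resp)
  for (i in seq_along(beats)) {
    f0 <- feet[i]
    f1 <- if (i < length(beats)) feet[i + 1] else f0 + 0.8
    i0 <- floor(f0 * fs) + 1L
    ip <- min(n, floor((f0 + .PPG_RISE) * fs) + 1L)
    i1 <- min(n, floor(f1 * fs))
    if (i0 >= i1 || i0 > n) next
    riseIdx <- i0:ip
    u <- ((riseIdx - 1) / fs - f0) / .PPG_RISE
    ppg[riseIdx] <- ppg[riseIdx] + ampPpg[i] * (1 - cos(pi * pmin(u, 1))) / 2
    if (ip < i1) {
      fallIdx <- (ip + 1L):i1
      v <- ((fallIdx - 1) / fs - (f0 + .PPG_RISE)) / max(f1 - f0 - .PPG_RISE,
                                                         0.05)
      ppg[fallIdx] <- ppg[fallIdx] + ampPpg[i] * exp(-3 * v)
    }
    ## AP systolic bump on top of the latent mean, zero-mean over the beat
    b0 <- floor(beats[i] * fs) + 1L
    b1 <- min(n, if (i < length(beats)) floor(beats[i + 1] * fs) else
      b0 + round(0.8 * fs))
    if (b0 < b1 && b0 >= 1L) {
      ub <- seq(0, 1, length.out = b1 - b0 + 1L)
      shape <- sin(pi * pmin(ub / 0.4, 1))^2 * exp(-2 * pmax(ub - 0.4, 0))
      ap[b0:b1] <- ap[b0:b1] + pp[i] * (shape - mean(shape))
    }
  }
  ap <- ap + rnorm(n, 0, config@obsNoiseSd * 10)
  svo2 <- latAt("svo2", tAxis) + rnorm(n, 0, 0.3)

  beatSeries <- data.frame(
    time = beats,
    map = latAt("map", beats) + rnorm(k, 0, 1.0),
    svv = 1.15 * ppvBeat + rnorm(k, 0, 0.5),
    ppv = ppvBeat + rnorm(k, 0, 0.3))

  new("SubjectRecord",
      subjectId = params@subjectId, fs = fs,
      channels = list(ecg = ecg, ppg = ppg, ap = ap, svo2 = svo2),
      beatSeries = beatSeries,
      stages = latentSim$stages,
      assessmentTimes = latentSim$assessments$time,
      truth = list(latent = lat, beatTimes = beats, footTimes = feet,
                   ptt = ptt, params = params, targets = latentSim$targets,
                   assessments = latentSim$assessments,
                   bolusTimes = latentSim$bolusTimes))
}
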