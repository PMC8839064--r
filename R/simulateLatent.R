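## Latent hemodynamic dynamics: piecewise-stationary trajectories of the
## "invasive truth" (MAP, SvO2, HR, PPV, SVV) on a 1-s grid, driven by a
## scalar severity state s in [0, ~1]: 0 = subject baseline, 1 = fully
## developed hemorrhagic shock (latent MAP near the 35 mmHg floor).

.MAP_FLOOR <- 35
.SVO2_FLOOR <- 35

#' Draw one subject's fixed simulation parameters
#'
#' Per-quantity additive shifts are Normal(0, `subjectShiftSd`) in
#' population-SD units and multiplicative scales are exp(Normal(0,
#' `subjectScaleSd`)); both are drawn once and fixed for the subject's
#' lifetime.  Bleeding sensitivity and bolus response get mild log-normal
#' subject-to-subject variation around their configured values.  Consumes the
#' current RNG stream, so results are deterministic given `set.seed()`.
#'
#' @param config a [CohortConfig-class].
#' @param quantities names of the tracked quantities; the five vitals for the
#'   waveform tier, [suffFeatureNames()] for the feature-level tier.
#' @param subjectId identifier.
#' @return A [SubjectParams-class].
#' @export
#' @examples
#' set.seed(1)
#' drawSubjectParams(cohortConfig(), subjectId = "S01")
drawSubjectParams <- function(config,
                              quantities = c("map", "hr", "svo2", "svv",
                                             "ppv"),
                              subjectId = "S1") {
  d <- length(quantities)
  shifts <- stats::setNames(rnorm(d, 0, config@subjectShiftSd), quantities)
  scales <- stats::setNames(exp(rnorm(d, 0, config@subjectScaleSd)),
                            quantities)
  new("SubjectParams", subjectId = subjectId,
      shifts = shifts, scales = scales,
      bleedSensitivity = config@bleedSensitivity * exp(rnorm(1, 0, 0.2)),
      bolusResponse = config@bolusResponse * exp(rnorm(1, 0, 0.25)))
}

## AR(1) noise continued across stage boundaries; stationary SD = sd.
.arNoise <- function(n, sd, last = 0, phi = 0.9) {
  if (n == 0L) return(list(x = numeric(0), last = last))
  if (sd <= 0) return(list(x = rep(0, n), last = 0))
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  x <- numeric(n)
  prev <- last
  for (i in seq_len(n)) {
    prev <- phi * prev + innov[i]
    x[i] <- prev
  }
  list(x = x, last = prev)
}

.subjectBaselines <- function(params, config) {
  v <- c("map", "hr", "svo2", "svv", "ppv")
  config@populationMeans[v] * params@scales[v] +
    params@shifts[v] * config@populationSds[v]
}

## Vitals as functions of severity.  SvO2 and MAP fall toward their floors;
## HR, PPV and SVV rise with sympathetic activation.
.vitalsAtSeverity <- function(s, base) {
  list(map  = base[["map"]]  - s * (base[["map"]]  - .MAP_FLOOR),
       svo2 = pmin(100, pmax(0, base[["svo2"]] -
                               s * (base[["svo2"]] - .SVO2_FLOOR))),
       hr   = base[["hr"]]  * (1 + 0.5 * s),
       ppv  = base[["ppv"]] * (1 + 1.2 * s),
       svv  = base[["svv"]] * (1 + 1.2 * s))
}

#' Simulate one subject's latent trajectory
#'
#' Piecewise dynamics on a 1-s grid.  Stable: stationary around the subject
#' baseline.  Bleeding: latent MAP declines at `bleedSensitivity` mmHg/s
#' until the first sample falls below `bleedMapStop`, which ends the stage
#' (exact first-crossing semantics); SvO2 falls and HR/PPV/SVV rise with the
#' severity state.  Waiting: near-stationary with a slow deepening drift.
#' Resuscitation: sufficiency is assessed every `assessmentInterval` s over
#' the preceding 2-min segment against the subject's stable-period targets;
#' each insufficient assessment triggers a 6-min bolus restoring
#' `bolusResponse` severity units (next assessment after
#' `assessmentIntervalBolus` s); the run ends once two consecutive
#' assessments are sufficient, or after `maxAssessments`.
#'
#' @param params a [SubjectParams-class] drawn over the five vitals.
#' @param config a [CohortConfig-class].
#' @return A list with elements `latent` (data.frame: time, map, svo2, hr,
#'   ppv, svv, deficit, severity, stage), `stages`, `assessments` (data.frame:
#'   time, label), `bolusTimes`, `targets`.
#' @export
simulateLatent <- function(params, config) {
  if (params@bleedSensitivity <= 0)
    stop("bleedSensitivity must be positive: bleeding would never terminate")
  base <- .subjectBaselines(params, config)
  nsd <- config@noiseSd * config@populationSds
  vits <- c("map", "hr", "svo2", "svv", "ppv")
  ar <- stats::setNames(rep(0, 5), vits)

  blocks <- list()
  emit <- function(t, s, stage) {
    n <- length(t)
    det <- .vitalsAtSeverity(s, base)
    noise <- lapply(vits, function(v) {
      r <- .arNoise(n, nsd[[v]], ar[[v]])
      ar[[v]] <<- r$last
      r$x
    })
    names(noise) <- vits
    data.frame(time = t,
               map = pmax(1, det$map + noise$map),
               svo2 = pmin(100, pmax(0, det$svo2 + noise$svo2)),
               hr = pmax(20, det$hr + noise$hr),
               ppv = pmax(0, det$ppv + noise$ppv),
               svv = pmax(0, det$svv + noise$svv),
               severity = s, stage = stage)
  }

  ## --- stable ---
  t0 <- seq(0, config@stableDuration - 1)
  blocks$stable <- emit(t0, rep(0, length(t0)), "stable")
  targets <- computeTargets(blocks$stable$map, blocks$stable$svo2,
                            kSd = config@kSd)

  ## --- bleeding: step until first MAP sample < bleedMapStop ---
  span <- base[["map"]] - .MAP_FLOOR
  tB <- config@stableDuration
  maxBleed <- ceiling(1.5 * span / params@bleedSensitivity) + 10
  sBleed <- pmin(params@bleedSensitivity * seq_len(maxBleed) / span, 1.1)
  det <- base[["map"]] - sBleed * span
  nz <- .arNoise(maxBleed, nsd[["map"]], ar[["map"]])
  mapPath <- pmax(1, det + nz$x)
  cross <- which(mapPath < config@bleedMapStop)
  if (length(cross) == 0L)
    stop("bleeding failed to reach bleedMapStop within the simulated horizon")
  nb <- cross[1]
  tBleed <- tB + seq_len(nb) - 1
  ## re-emit with all channels, severity from the deterministic decline
  bl <- emit(tBleed, sBleed[seq_len(nb)], "bleeding")
  bl$map <- mapPath[seq_len(nb)]         # keep the exact crossing path
  ar[["map"]] <- nz$x[nb]
  blocks$bleeding <- bl
  sEnd <- sBleed[nb]

  ## --- waiting: slow deepening drift ---
  tW <- max(bl$time) + 1
  tw <- seq(tW, tW + config@waitingDuration - 1)
  sWait <- pmin(1.1, sEnd + 3e-6 * (tw - tW))
  blocks$waiting <- emit(tw, sWait, "waiting")

  ## --- resuscitation: assessment/bolus event loop ---
  tR <- max(tw) + 1
  s <- sWait[length(sWait)]
  resus <- list(); assessT <- numeric(); assessL <- character()
  bolusT <- numeric(); sufficientRun <- 0L
  tNow <- tR
  nextAssess <- tR + config@assessmentInterval
  bolusEnd <- -Inf; bolusRate <- 0
  deficitRate <- 10 / 60                       # mL/s while bleeding
  repeat {
    n <- nextAssess - tNow
    tt <- seq(tNow, nextAssess - 1)
    sSeg <- numeric(n)
    for (i in seq_len(n)) {
      if (tt[i] < bolusEnd) s <- max(0, s - bolusRate)
      sSeg[i] <- s
    }
    resus[[length(resus) + 1L]] <- emit(tt, sSeg, "resuscitation")
    tNow <- nextAssess
    ## assess over the preceding 120 s
    recent <- do.call(rbind, resus)
    seg <- recent[recent$time >= tNow - 120 & recent$time < tNow, ]
    lab <- labelSegment(mean(seg$map), mean(seg$svo2), targets)
    assessT <- c(assessT, tNow); assessL <- c(assessL, lab)
    if (lab == "sufficient") {
      sufficientRun <- sufficientRun + 1L
      if (sufficientRun >= 2L || length(assessT) >= config@maxAssessments)
        break
      nextAssess <- tNow + config@assessmentInterval
    } else {
      sufficientRun <- 0L
      if (length(assessT) >= config@maxAssessments) break
      bolusT <- c(bolusT, tNow)
      bolusEnd <- tNow + config@bolusDuration
      bolusRate <- params@bolusResponse / config@bolusDuration
      nextAssess <- tNow + config@assessmentIntervalBolus
    }
  }
  blocks$resus <- do.call(rbind, resus)

  latent <- do.call(rbind, blocks)
  rownames(latent) <- NULL
  ## volume deficit: integrates the 10 mL/min bleed, drained by boluses
  bleedMask <- latent$stage == "bleeding"
  deficit <- cumsum(ifelse(bleedMask, deficitRate, 0))
  for (b in bolusT) {
    idx <- latent$time >= b & latent$time < b + config@bolusDuration
    deficit <- deficit - cumsum(ifelse(idx, 500 / config@bolusDuration, 0))
  }
  latent$deficit <- pmax(0, deficit)
  latent <- latent[, c("time", "map", "svo2", "hr", "ppv", "svv",
                       "deficit", "severity", "stage")]

  stageTab <- do.call(rbind, lapply(split(latent, latent$stage), function(d)
    data.frame(stage = d$stage[1], start = min(d$time),
               end = max(d$time) + 1)))
  stageTab <- stageTab[order(stageTab$start), ]
  rownames(stageTab) <- NULL

  list(latent = latent, stages = stageTab,
       assessments = data.frame(time = assessT, label = assessL),
       bolusTimes = bolusT, targets = targets)
}
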