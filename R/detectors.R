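## Fiducial detection: R peaks from ECG, foot/peak geometry from PPG, and
## pulse transit time.  Classical, dependency-light algorithms adequate for
## the stylized simulated morphology and pinned for reproducibility.

#' Detect ECG R peaks
#'
#' Band-pass (5--30 Hz Butterworth, zero-phase), squared derivative energy,
#' 150-ms moving-average smoothing, adaptive threshold at a fraction of the
#' upper energy quantile, then local-maximum extraction with a 200-ms
#' refractory rule (the larger peak wins) and peak refinement on the raw
#' signal.
#'
#' @param ecg numeric waveform.
#' @param fs sampling rate, Hz.
#' @return Strictly increasing peak times in seconds; `numeric(0)` (with a
#'   warning) for flat or non-finite signals.
#' @export
detectRPeaks <- function(ecg, fs) {
  if (length(ecg) < 5 * fs)
    stop("need at least 5 s of ECG")
  if (any(!is.finite(ecg)) || sd(ecg) < 1e-12) {
    warning("flat or non-finite ECG; no beats detected")
    return(numeric(0))
  }
  bf <- signal::butter(2, c(5, 30) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bf, ecg)
  e <- c(0, diff(f))^2
  w <- max(1L, round(0.15 * fs))
  sm <- stats::filter(e, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  thr <- 0.2 * .q(sm, 0.99)
  if (thr <= 0) {
    warning("no QRS energy above threshold")
    return(numeric(0))
  }
  isPk <- sm > thr &
    sm >= c(-Inf, sm[-length(sm)]) & sm >= c(sm[-1], -Inf)
  cand <- which(isPk)
  if (length(cand) == 0L) return(numeric(0))
  ## refractory: sweep in time, keep the larger of peaks closer than 200 ms
  refr <- 0.2 * fs
  keep <- cand[1]
  for (i in cand[-1]) {
    lastI <- keep[length(keep)]
    if (i - lastI >= refr) keep <- c(keep, i)
    else if (sm[i] > sm[lastI]) keep[length(keep)] <- i
  }
  ## refine on the raw signal within +/- 60 ms
  half <- round(0.06 * fs)
  refined <- vapply(keep, function(i) {
    i0 <- max(1L, i - half); i1 <- min(length(ecg), i + half)
    i0 + which.max(ecg[i0:i1]) - 1L
  }, numeric(1))
  refined <- sort(unique(refined))
  ## refractory again after refinement
  if (length(refined) > 1L) {
    out <- refined[1]
    for (i in refined[-1]) {
      if (i - out[length(out)] >= refr) out <- c(out, i)
      else if (ecg[i] > ecg[out[length(out)]]) out[length(out)] <- i
    }
    refined <- out
  }
  (refined - 1) / fs
}

#' Locate PPG pulse fiducials and per-beat geometry
#'
#' For each beat interval (R peak to next R peak) the pulse foot is the
#' signal minimum over the first 60% of the interval and the peak the
#' maximum after the foot.  Beats whose extrema sit on the search-interval
#' boundary, or with non-positive amplitude, are flagged missing.  Geometry
#' per accepted beat: systolic amplitude (peak - foot), rise time
#' (foot to peak), width at half amplitude, pulse area above the foot value
#' (trapezoidal, foot to next foot), and downslope time (peak to next foot).
#'
#' @param ppg numeric waveform.
#' @param fs sampling rate, Hz.
#' @param beatTimes R-peak times, s.
#' @return data.frame, one row per beat: tFoot, tPeak, vFoot, vPeak, amp,
#'   rise, width, area, fall, ok.
#' @export
detectPPGFiducials <- function(ppg, fs, beatTimes) {
  nb <- length(beatTimes)
  out <- data.frame(tFoot = rep(NA_real_, nb), tPeak = NA_real_,
                    vFoot = NA_real_, vPeak = NA_real_, amp = NA_real_,
                    rise = NA_real_, width = NA_real_, area = NA_real_,
                    fall = NA_real_, ok = FALSE)
  if (nb == 0L) return(out)
  rr <- if (nb > 1L) median(diff(beatTimes)) else 0.8
  nextBeat <- c(beatTimes[-1], beatTimes[nb] + rr)
  n <- length(ppg)
  toIdx <- function(t) pmax(1L, pmin(n, floor(t * fs) + 1L))
  for (i in seq_len(nb)) {
    i0 <- toIdx(beatTimes[i])
    iMid <- toIdx(beatTimes[i] + 0.6 * (nextBeat[i] - beatTimes[i]))
    i1 <- toIdx(nextBeat[i])
    if (iMid - i0 < 3L || i1 - i0 < 5L) next
    seg <- ppg[i0:iMid]
    fIdx <- i0 + which.min(seg) - 1L
    pSeg <- ppg[fIdx:i1]
    pIdx <- fIdx + which.max(pSeg) - 1L
    if (pIdx <= fIdx || pIdx >= i1 || fIdx >= iMid) next
    vF <- ppg[fIdx]; vP <- ppg[pIdx]
    if (vP - vF <= 0) next
    ## next foot: minimum over the first 60% of the following interval
    j1 <- toIdx(nextBeat[i] + 0.6 * rr)
    nfIdx <- if (j1 > i1 + 2L) i1 + which.min(ppg[i1:j1]) - 1L else i1
    half <- vF + (vP - vF) / 2
    above <- which(ppg[fIdx:nfIdx] >= half)
    width <- if (length(above)) (max(above) - min(above)) / fs else NA_real_
    area <- sum(pmax(ppg[fIdx:nfIdx] - vF, 0)) / fs
    out[i, ] <- list((fIdx - 1) / fs, (pIdx - 1) / fs, vF, vP, vP - vF,
                     (pIdx - fIdx) / fs, width, area,
                     (nfIdx - pIdx) / fs, TRUE)
  }
  out
}

#' Pulse transit time per beat
#'
#' PTT is the delay from each ECG R peak to the foot of the corresponding
#' PPG pulse.  Beats with no matched foot, or a foot at or before the R peak,
#' are missing.
#'
#' @param rTimes R-peak times, s.
#' @param footTimes matched PPG foot times, s (same length, NA allowed).
#' @return numeric vector of positive transit times (NA where unmatched).
#' @export
computePTT <- function(rTimes, footTimes) {
  if (length(rTimes) != length(footTimes))
    stop("rTimes and footTimes must be matched per beat")
  ptt <- footTimes - rTimes
  ptt[!is.na(ptt) & ptt <= 0] <- NA_real_
  ptt
}
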