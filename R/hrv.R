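## Heart-rate-variability scalars over one window's NN intervals.

## Classical Lomb-Scargle periodogram (normalized by 2*variance), evaluated
## on a pinned grid; band power integrates the density over the band.
.lombPower <- function(times, x, fLo, fHi, df = 0.01) {
  xm <- x - mean(x)
  v <- var(x)
  if (!is.finite(v) || v <= 0) return(0)
  freqs <- seq(0.04, 0.40, by = df)
  p <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    ct <- cos(w * (times - tau)); st <- sin(w * (times - tau))
    (sum(xm * ct)^2 / sum(ct^2) + sum(xm * st)^2 / sum(st^2)) / (2 * v)
  }, numeric(1))
  dens <- p * 2 * v / length(x)         # to absolute units (s^2/Hz)
  inBand <- freqs >= fLo & freqs < fHi
  sum(dens[inBand]) * df
}

#' Window-level heart-rate-variability metrics
#'
#' Standard definitions over the NN (inter-beat) intervals of one window:
#' meanNN; SDNN (SD, n-1 denominator); RMSSD (root mean square of successive
#' differences); pNN50 (fraction of successive differences exceeding 50 ms);
#' CVNN = SDNN / meanNN; Poincare axes SD1 = RMSSD / sqrt(2) and
#' SD2 = sqrt(2 SDNN^2 - SD1^2) with their ratio; the HRV triangular index
#' (interval count divided by the modal bin height of a 1/128-s histogram);
#' and LF (0.04--0.15 Hz) and HF (0.15--0.40 Hz) Lomb-Scargle band powers
#' with their ratio.  Spectral indices on 20-s windows are statistically
#' noisy, LF especially; they are retained for completeness of the feature
#' family and flagged as such in the vignette.
#'
#' @param rr NN intervals in seconds.
#' @return Named numeric of length 12 ([suffFeatureNames()] HRV block);
#'   all-NA when fewer than 3 intervals are available.
#' @export
#' @examples
#' computeHRVMetrics(c(0.8, 0.82, 0.78, 0.85, 0.8))
computeHRVMetrics <- function(rr) {
  out <- stats::setNames(rep(NA_real_, length(.HRV_NAMES)), .HRV_NAMES)
  rr <- rr[is.finite(rr)]
  if (length(rr) < 3L) return(out)
  dif <- diff(rr)
  meanNN <- mean(rr)
  sdnn <- sd(rr)
  rmssd <- sqrt(mean(dif^2))
  sd1 <- rmssd / sqrt(2)
  sd2sq <- 2 * sdnn^2 - sd1^2
  sd2 <- sqrt(max(sd2sq, 0))
  binW <- 1 / 128
  counts <- table(floor(rr / binW))
  tri <- length(rr) / max(counts)
  beatT <- cumsum(rr)
  lf <- .lombPower(beatT, rr, 0.04, 0.15)
  hf <- .lombPower(beatT, rr, 0.15, 0.40)
  out[] <- c(meanNN, sdnn, rmssd, mean(abs(dif) > 0.05), sdnn / meanNN,
             sd1, sd2, if (sd2 > 0) sd1 / sd2 else NA_real_, tri,
             lf, hf, if (hf > 0) lf / hf else NA_real_)
  out
}

#' Median, IQR and slope of a beat series within a window
#'
#' The three aggregates used for every beat-to-beat channel: median and
#' inter-quartile range with linear-interpolation quantiles, and the
#' ordinary-least-squares slope of value against time (units per second).
#'
#' @param values per-beat values.
#' @param times matching beat times, s.
#' @return Named numeric: median, iqr, slope; all NA when fewer than 2
#'   non-missing values remain.
#' @export
#' @examples
#' aggregateBeatSeries(c(1, 2, 3), c(0, 10, 20))  # 2, 1, 0.1
aggregateBeatSeries <- function(values, times) {
  ok <- is.finite(values) & is.finite(times)
  if (sum(ok) < 2L)
    return(c(median = NA_real_, iqr = NA_real_, slope = NA_real_))
  v <- values[ok]; t <- times[ok]
  slope <- if (var(t) > 0) cov(t, v) / var(t) else 0
  c(median = median(v), iqr = .q(v, 0.75) - .q(v, 0.25), slope = slope)
}
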