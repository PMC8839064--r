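## Canonical 42-feature dictionary shared by both simulator tiers and the
## featurizer.  Ordering is part of the serialized format: do not reorder.

.BEAT_CHANNELS <- c("map", "svv", "ppv", "hr", "ptt")
.PPG_CHANNELS  <- c("ppg_amp", "ppg_rise", "ppg_width", "ppg_area", "ppg_fall")
.AGG_STATS     <- c("median", "iqr", "slope")
.HRV_NAMES <- c("hrv_mean_nn", "hrv_sdnn", "hrv_rmssd", "hrv_pnn50",
                "hrv_cvnn", "hrv_sd1", "hrv_sd2", "hrv_sd1_sd2",
                "hrv_tri", "hrv_lf", "hrv_hf", "hrv_lf_hf")

#' Canonical window-feature names
#'
#' The fixed, versioned ordering of the 42 window-level features: five
#' beat-to-beat channels (MAP, SVV, PPV, HR, PTT) and five PPG pulse-geometry
#' channels (systolic amplitude, rise time, width at half amplitude, pulse
#' area, downslope time), each aggregated as median / IQR / linear slope
#' within the window, plus 12 HRV scalars.
#'
#' @return Character vector of length 42.
#' @export
#' @examples
#' length(suffFeatureNames())
suffFeatureNames <- function() {
  c(as.vector(t(outer(.BEAT_CHANNELS, .AGG_STATS, paste, sep = "_"))),
    as.vector(t(outer(.PPG_CHANNELS, .AGG_STATS, paste, sep = "_"))),
    .HRV_NAMES)
}

#' Hash of the canonical feature ordering
#'
#' 32-bit FNV-1a hash of the concatenated canonical feature names, written
#' into manifests and checked when feature matrices are read back, so that a
#' stored artifact produced under a different feature ordering is rejected.
#'
#' @return A character scalar, eight hex digits.
#' @export
featureOrderHash <- function() .stringHash(paste(suffFeatureNames(),
                                                 collapse = "|"))

## 32-bit polynomial rolling hash (base 31), exact in double arithmetic
.stringHash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

## Feature-tier generative dictionary: per-feature baseline level, within-class
## SD (the unit of subject shifts and observation noise), and standardized
## severity loading (expected change, in SDs, between a stable subject and one
## in fully developed hemorrhagic shock).  Signs follow hemodynamics: bleeding
## lowers MAP, PPG amplitude/area and HRV, raises HR, PPV, SVV and PTT.
.featureModel <- function() {
  m <- rbind(
    map_median  = c(85,    6,    -1.8),
    map_iqr     = c(4,     1.2,   0.3),
    map_slope   = c(0,     0.05, -0.3),
    svv_median  = c(8,     2,     1.3),
    svv_iqr     = c(1.5,   0.5,   0.3),
    svv_slope   = c(0,     0.10,  0.1),
    ppv_median  = c(9,     2,     1.5),
    ppv_iqr     = c(1.5,   0.5,   0.3),
    ppv_slope   = c(0,     0.10,  0.1),
    hr_median   = c(90,    8,     1.6),
    hr_iqr      = c(3,     1,     0.4),
    hr_slope    = c(0,     0.05,  0.1),
    ptt_median  = c(0.20,  0.02,  0.9),
    ptt_iqr     = c(0.010, 0.004, 0.2),
    ptt_slope   = c(0,     0.001, 0.0),
    ppg_amp_median   = c(1.0,  0.15,  -1.2),
    ppg_amp_iqr      = c(0.10, 0.03,   0.2),
    ppg_amp_slope    = c(0,    0.01,   0.0),
    ppg_rise_median  = c(0.15, 0.020,  0.4),
    ppg_rise_iqr     = c(0.010, 0.004, 0.1),
    ppg_rise_slope   = c(0,    0.001,  0.0),
    ppg_width_median = c(0.25, 0.03,   0.3),
    ppg_width_iqr    = c(0.020, 0.006, 0.1),
    ppg_width_slope  = c(0,    0.001,  0.0),
    ppg_area_median  = c(0.35, 0.08,  -1.0),
    ppg_area_iqr     = c(0.050, 0.015, 0.2),
    ppg_area_slope   = c(0,    0.005,  0.0),
    ppg_fall_median  = c(0.45, 0.05,  -0.5),
    ppg_fall_iqr     = c(0.030, 0.010, 0.1),
    ppg_fall_slope   = c(0,    0.002,  0.0),
    hrv_mean_nn = c(0.67,  0.06,  -1.5),
    hrv_sdnn    = c(0.030, 0.010, -0.9),
    hrv_rmssd   = c(0.025, 0.008, -0.9),
    hrv_pnn50   = c(0.05,  0.03,  -0.4),
    hrv_cvnn    = c(0.045, 0.012, -0.5),
    hrv_sd1     = c(0.018, 0.006, -0.9),
    hrv_sd2     = c(0.040, 0.012, -0.7),
    hrv_sd1_sd2 = c(0.45,  0.10,  -0.2),
    hrv_tri     = c(4,     1,     -0.5),
    hrv_lf      = c(0.002, 0.001, -0.3),
    hrv_hf      = c(0.003, 0.001, -0.6),
    hrv_lf_hf   = c(0.8,   0.3,    0.3)
  )
  colnames(m) <- c("base", "sd", "loading")
  stopifnot(identical(rownames(m), suffFeatureNames()))
  m
}
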