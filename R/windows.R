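#' Enumerate moving windows within a segment
#'
#' Windows of `win` seconds starting every `stride` seconds at
#' `segmentStart + k * stride`; a window must fit fully inside the segment.
#' A 120-s segment therefore yields 11 windows of 20 s at a 10-s stride, and
#' in general `floor((L - win) / stride) + 1` for segment length `L >= win`.
#'
#' @param segmentStart,segmentEnd seconds.
#' @param win window length, s (default 20).
#' @param stride step between window starts, s (default 10).
#' @return data.frame with columns start, end, ordered; empty (with a
#'   warning) if the segment is shorter than one window.
#' @export
#' @examples
#' nrow(extractWindows(0, 120))  # 11
extractWindows <- function(segmentStart, segmentEnd, win = 20, stride = 10) {
  L <- segmentEnd - segmentStart
  if (L < win) {
    warning("segment shorter than one window; no windows extracted")
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  k <- 0:floor((L - win) / stride)
  starts <- segmentStart + k * stride
  data.frame(start = starts, end = starts + win)
}
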