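## Heart-rate estimation from raw pulse-oximetry (PPG) segments.
##
## Adaptive-threshold peak detection in the spirit of the established PPG
## toolkits: the signal is detrended against a 0.75 s moving average and
## lightly smoothed (0.12 s moving average, which suppresses sample noise
## that would split one beat region into two while leaving the 0.3-3 Hz
## beat structure intact); beats are the maxima of contiguous regions
## exceeding an offset, and the offset is chosen from a grid to minimize
## the standard deviation of the inter-beat intervals (the most regular
## beat train wins). The symmetric smoother shifts every peak by the same
## sub-sample amount, so inter-beat intervals are unaffected.

#' Estimate beats-per-minute heart rate from a PPG segment
#'
#' @param segment data frame with columns `time_s` (uniform sampling) and
#'   `value`.
#' @param offsets candidate threshold offsets as fractions of the maximum
#'   detrended amplitude.
#' @return a one-row data frame of class `oc_hr`: `bpm`, `n_beats`,
#'   `ibi_cv` (coefficient of variation of inter-beat intervals),
#'   `quality_ok` and `rejection_reason`. `quality_ok` is `FALSE` when the
#'   estimate falls outside 40-180 bpm, fewer than 10 beats were found, the
#'   interval CV exceeds 0.5, or the segment is flat/too short
#'   (`"insufficient signal"`).
#' @export
estimate_heart_rate <- function(segment, offsets = seq(0.1, 0.7, by = 0.05)) {
  bad <- function(reason)
    structure(data.frame(bpm = NA_real_, n_beats = 0L, ibi_cv = NA_real_,
                         quality_ok = FALSE, rejection_reason = reason),
              class = c("oc_hr", "data.frame"))
  if (!all(c("time_s", "value") %in% names(segment)))
    stop("segment needs `time_s` and `value` columns")
  n <- nrow(segment)
  if (n < 3L) return(bad("insufficient signal"))
  fs <- 1 / (segment$time_s[2] - segment$time_s[1])
  if (n / fs < 10) return(bad("insufficient signal"))
  x <- segment$value
  d <- x - moving_average(x, round(0.75 * fs))
  d <- moving_average(d, round(0.12 * fs))
  amp <- max(d, na.rm = TRUE)
  if (!is.finite(amp) || amp <= 10 * .Machine$double.eps * max(abs(x), 1))
    return(bad("insufficient signal"))

  best <- NULL; best_sd <- Inf
  for (off in offsets * amp) {
    pk <- region_peaks(d, off)
    if (length(pk) < 3L) next
    ibi <- diff(segment$time_s[pk])
    s <- sd(ibi)
    if (s < best_sd) { best_sd <- s; best <- pk }
  }
  if (is.null(best)) return(bad("no stable beat train"))
  ibi <- diff(segment$time_s[best])
  bpm <- 60 / mean(ibi)
  cv <- sd(ibi) / mean(ibi)
  ok <- bpm >= 40 && bpm <= 180 && length(best) >= 10L && cv <= 0.5
  reason <- if (ok) "" else if (length(best) < 10L) "too few beats" else
    if (cv > 0.5) "irregular intervals" else "rate out of range"
  structure(data.frame(bpm = bpm, n_beats = length(best), ibi_cv = cv,
                       quality_ok = ok, rejection_reason = reason),
            class = c("oc_hr", "data.frame"))
}

## indices of the maximum of each contiguous region where x > threshold
region_peaks <- function(x, threshold) {
  above <- x > threshold
  if (!any(above)) return(integer(0))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  vapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    idx[which.max(x[idx])]
  }, integer(1))
}
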