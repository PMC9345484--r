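## Oculomotor event classification: velocity-based fixation/saccade
## segmentation with an adaptive threshold, amplitude/duration merging
## criteria, and blink detection from pupil signal loss.

## columns shared by all event tables; the position/velocity sufficient
## statistics allow merged events to be recomputed without the raw trace
EVENT_COLS <- c("kind", "onset", "offset", "duration", "amplitude",
                "peak_velocity", "mean_velocity", "n_samples",
                "x_on", "y_on", "x_off", "y_off", "v_sum", "v_max", "segment")

as_event_table <- function(df) {
  for (cl in setdiff(EVENT_COLS, names(df)))
    df[[cl]] <- rep(NA_real_, nrow(df))
  df <- df[EVENT_COLS]
  class(df) <- c("oc_events", "data.frame")
  df
}

#' Smooth a gaze recording and derive instantaneous speed
#'
#' x and y are Savitzky-Golay smoothed independently within each contiguous
#' segment of valid data (pupil present); speed is the Euclidean norm of the
#' first differences of the smoothed positions, scaled by the sampling rate
#' and converted to degrees of visual angle (0.0186 deg/px). Segments shorter
#' than the filter window pass through unsmoothed (with a message). The first
#' sample of each segment repeats the following speed value so that speed has
#' the same length as the recording; speed is missing wherever gaze is
#' missing. A pupil value of 0 and a non-finite pupil value both mean
#' "missing".
#'
#' @param rec gaze recording: data frame with columns `time_ms` (uniform
#'   steps), `x_px`, `y_px`, `pupil`.
#' @param window,polyorder Savitzky-Golay parameters (samples / degree);
#'   defaults 21 and 2 preserve saccade velocity peaks at 1 kHz.
#' @return data frame `time_ms`, `x_smooth`, `y_smooth`, `speed` (deg/s)
#'   with attribute `dt_ms`, class `oc_velocity`.
#' @export
smooth_gaze <- function(rec, window = 21L, polyorder = 2L) {
  stopifnot(all(c("time_ms", "x_px", "y_px", "pupil") %in% names(rec)))
  n <- nrow(rec)
  if (n < 2L) stop("recording too short")
  dt_ms <- rec$time_ms[2] - rec$time_ms[1]
  if (dt_ms <= 0) stop("time must be strictly increasing")
  fs <- 1000 / dt_ms
  miss <- !is.finite(rec$pupil) | rec$pupil == 0 |
    !is.finite(rec$x_px) | !is.finite(rec$y_px)
  xs <- ys <- speed <- rep(NA_real_, n)
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(!runs$values)) {
    idx <- starts[k]:ends[k]
    if (length(idx) < 2L) next
    xs[idx] <- savgol_smooth(rec$x_px[idx], window, polyorder)
    ys[idx] <- savgol_smooth(rec$y_px[idx], window, polyorder)
    sp <- sqrt(diff(xs[idx])^2 + diff(ys[idx])^2) * fs * DEG_PER_PX
    speed[idx] <- c(sp[1], sp)
  }
  structure(data.frame(time_ms = rec$time_ms, x_smooth = xs, y_smooth = ys,
                       speed = speed),
            dt_ms = dt_ms, class = c("oc_velocity", "data.frame"))
}

#' Adaptive velocity threshold
#'
#' Iterates `T <- mean + 6 * SD` of all speeds below the current `T`,
#' starting from `init_threshold`, until the update changes by less than
#' `tol` or `max_iter` iterations are reached. The data-driven threshold
#' separates the slow (fixation) and fast (saccade) velocity modes without a
#' hand-picked cut-off.
#'
#' @param trace velocity trace from [smooth_gaze()].
#' @param init_threshold starting threshold, deg/s.
#' @param tol convergence tolerance, deg/s.
#' @param max_iter iteration cap.
#' @return threshold in deg/s, with attribute `converged`.
#' @export
adaptive_velocity_threshold <- function(trace, init_threshold = 100,
                                        tol = 1, max_iter = 100L) {
  s <- trace$speed[is.finite(trace$speed)]
  if (length(s) < 100L) stop("need at least 100 valid speed samples")
  thr <- init_threshold
  for (i in seq_len(max_iter)) {
    below <- s[s < thr]
    if (length(below) == 0L) {
      if (i == 1L) {
        warning("no speeds below the initial threshold; returning it")
        return(structure(init_threshold, converged = FALSE))
      }
      return(structure(thr, converged = TRUE))
    }
    sdv <- if (length(below) > 1L) sd(below) else 0
    new_thr <- mean(below) + 6 * sdv
    if (abs(new_thr - thr) < tol)
      return(structure(new_thr, converged = TRUE))
    thr <- new_thr
  }
  warning("adaptive threshold did not converge within ", max_iter,
          " iterations")
  structure(thr, converged = FALSE)
}

#' Classify candidate fixation and saccade phases
#'
#' Maximal runs of speed below the threshold become fixation candidates and
#' runs at or above it saccade candidates. Missing samples (blink gaps)
#' belong to neither and truncate adjacent candidates; candidates never span
#' a gap. Each candidate carries sufficient statistics (endpoint positions,
#' speed sum/max, sample count) so merging can recompute metrics without the
#' raw trace.
#'
#' @param trace velocity trace from [smooth_gaze()].
#' @param threshold velocity threshold in deg/s (> 0).
#' @return event table of class `oc_events` (columns `kind`, `onset`,
#'   `offset` in ms with half-open spans, `duration`, `amplitude` in deg,
#'   `peak_velocity`, `mean_velocity` in deg/s, internal statistics and a
#'   gap-separated `segment` id).
#' @export
classify_candidates <- function(trace, threshold) {
  if (threshold <= 0) stop("`threshold` must be positive")
  n <- nrow(trace)
  dt_ms <- attr(trace, "dt_ms")
  if (n == 0L) return(as_event_table(data.frame(kind = character(0))))
  cls <- ifelse(is.finite(trace$speed),
                ifelse(trace$speed < threshold, 0L, 1L), 2L)
  runs <- rle(cls)
  nr <- length(runs$values)
  seg_of_run <- cumsum(c(0L, head(runs$values, -1L) == 2L))
  dt_ <- data.table(
    id = rep(seq_len(nr), runs$lengths),
    t = trace$time_ms, x = trace$x_smooth, y = trace$y_smooth,
    sp = trace$speed)
  keep <- which(runs$values != 2L)
  if (length(keep) == 0L) return(as_event_table(data.frame(kind = character(0))))
  ev <- dt_[id %in% keep,
            .(onset = t[1L], n_samples = as.numeric(.N),
              x_on = x[1L], y_on = y[1L], x_off = x[.N], y_off = y[.N],
              v_sum = sum(sp), v_max = max(sp)),
            by = id]
  ev[, `:=`(kind = ifelse(runs$values[id] == 0L, "fixation", "saccade"),
            segment = seg_of_run[id])]
  ev[, `:=`(offset = onset + n_samples * dt_ms,
            amplitude = sqrt((x_off - x_on)^2 + (y_off - y_on)^2) * DEG_PER_PX,
            peak_velocity = v_max, mean_velocity = v_sum / n_samples)]
  ev[, duration := offset - onset]
  out <- as.data.frame(ev[order(onset)])
  out$id <- NULL
  as_event_table(out)
}

## One merging pass. `mergeable` marks events that may take part in a merge
## (the small events being dissolved plus the kind that absorbs them);
## maximal runs of mergeable events within a segment that contain at least
## one small event collapse into a single event of `merge_kind`. A run with
## no event of `merge_kind` (a small event with no partner, e.g. an isolated
## segment) is dropped. Runs never cross segment (gap) boundaries.
## Amplitude of a merged fixation is the displacement between the endpoints
## of the merged span ("displacement"); a merged saccade takes the SUM of
## its member saccade amplitudes ("sum"): every member is above the
## amplitude floor after pass 1, so the merged saccade provably stays above
## it too.
merge_pass <- function(ev, mergeable, is_small, merge_kind, amplitude_rule) {
  n <- nrow(ev)
  new_run <- c(TRUE, mergeable[-1L] != mergeable[-n] |
                 ev$segment[-1L] != ev$segment[-n])
  run_id <- cumsum(new_run)
  runs <- split(seq_len(n), run_id)
  active <- which(vapply(runs, function(ix) any(is_small[ix]), logical(1)) &
                    vapply(runs, function(ix) all(mergeable[ix]), logical(1)))
  if (length(active) == 0L) return(ev)
  blocks <- runs[active]
  blocks <- blocks[vapply(blocks, function(ix) any(ev$kind[ix] == merge_kind),
                          logical(1))] # partnerless small events are dropped
  keep <- ev[unlist(runs[-active], use.names = FALSE), , drop = FALSE]
  if (length(blocks) == 0L) {
    out <- keep
  } else {
    stats <- vapply(blocks, function(ix) {
      nb <- length(ix)
      amp <- if (amplitude_rule == "displacement") {
        sqrt((ev$x_off[ix[nb]] - ev$x_on[ix[1]])^2 +
               (ev$y_off[ix[nb]] - ev$y_on[ix[1]])^2) * DEG_PER_PX
      } else {
        sum(ev$amplitude[ix][ev$kind[ix] == "saccade"])
      }
      c(ev$onset[ix[1]], ev$offset[ix[nb]],
        ev$offset[ix[nb]] - ev$onset[ix[1]], amp,
        max(ev$v_max[ix]), sum(ev$v_sum[ix]) / sum(ev$n_samples[ix]),
        sum(ev$n_samples[ix]), ev$x_on[ix[1]], ev$y_on[ix[1]],
        ev$x_off[ix[nb]], ev$y_off[ix[nb]], sum(ev$v_sum[ix]),
        max(ev$v_max[ix]), ev$segment[ix[1]])
    }, numeric(14))
    collapsed <- data.frame(kind = merge_kind, t(stats))
    names(collapsed) <- EVENT_COLS
    out <- rbind(keep, collapsed)
  }
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the amplitude and duration merging criteria
#'
#' Two sequential passes, each run to completion. Pass 1: every saccade
#' candidate with amplitude below `min_amp_deg` (default 1 degree) is removed
#' and its flanking fixations merge into one fixation whose metrics are
#' recomputed over the merged span. Pass 2: every fixation candidate shorter
#' than `min_fix_ms` (default 60 ms) is removed and its flanking saccades
#' merge into one saccade. Both rules use strict inequalities, so events at
#' exactly the floor are kept. Merging never crosses a blink/data-loss gap.
#' After merging, every saccade has amplitude >= `min_amp_deg` and every
#' fixation duration >= `min_fix_ms`, and the fixation/saccade stream
#' alternates within each segment.
#'
#' @param candidates event table from [classify_candidates()].
#' @param min_amp_deg saccade amplitude floor, degrees.
#' @param min_fix_ms fixation duration floor, ms.
#' @return merged event table of class `oc_events`.
#' @export
merge_events <- function(candidates, min_amp_deg = 1.0, min_fix_ms = 60) {
  ev <- as.data.frame(candidates)
  if (nrow(ev) == 0L) return(as_event_table(ev))
  ## pass 1: dissolve small saccades into their neighbouring fixations
  small_sac <- ev$kind == "saccade" & ev$amplitude < min_amp_deg
  if (any(small_sac))
    ev <- merge_pass(ev, mergeable = ev$kind == "fixation" | small_sac,
                     is_small = small_sac, merge_kind = "fixation",
                     amplitude_rule = "displacement")
  ## pass 2: dissolve short fixations into their neighbouring saccades
  small_fix <- ev$kind == "fixation" & ev$duration < min_fix_ms
  if (any(small_fix))
    ev <- merge_pass(ev, mergeable = ev$kind == "saccade" | small_fix,
                     is_small = small_fix, merge_kind = "saccade",
                     amplitude_rule = "sum")
  as_event_table(ev)
}

#' Detect blinks as bounded gaps in the pupil signal
#'
#' Maximal runs of missing pupil data lasting between `min_ms` and `max_ms`
#' (inclusive on both sides) become blink events; shorter or longer gaps are
#' treated as data loss, not blinks. A pupil value of 0 and a non-finite
#' value both count as missing.
#'
#' @param rec gaze recording (see [smooth_gaze()]).
#' @param min_ms,max_ms blink duration bounds in ms (defaults 30 and 3000).
#' @return event table of class `oc_events` with `kind = "blink"`;
#'   amplitude/velocity columns are `NA`.
#' @export
detect_blinks <- function(rec, min_ms = 30, max_ms = 3000) {
  n <- nrow(rec)
  if (n == 0L) return(as_event_table(data.frame(kind = character(0))))
  dt_ms <- if (n > 1L) rec$time_ms[2] - rec$time_ms[1] else 1
  miss <- !is.finite(rec$pupil) | rec$pupil == 0
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values &
                  runs$lengths * dt_ms >= min_ms &
                  runs$lengths * dt_ms <= max_ms)
  if (length(keep) == 0L) return(as_event_table(data.frame(kind = character(0))))
  onset <- rec$time_ms[starts[keep]]
  dur <- runs$lengths[keep] * dt_ms
  as_event_table(data.frame(kind = "blink", onset = onset,
                            offset = onset + dur, duration = dur))
}

#' Metrics of a single event span
#'
#' Computes duration (ms), amplitude (degrees, Euclidean distance between the
#' first and last smoothed positions) and peak/mean velocity (deg/s) over the
#' samples with `onset_ms <= time <= offset_ms`.
#'
#' @param onset_ms,offset_ms span boundaries in ms.
#' @param trace velocity trace from [smooth_gaze()].
#' @return one-row data frame `duration`, `amplitude`, `peak_velocity`,
#'   `mean_velocity`.
#' @export
event_metrics <- function(onset_ms, offset_ms, trace) {
  idx <- which(trace$time_ms >= onset_ms & trace$time_ms <= offset_ms)
  if (length(idx) < 2L) stop("span covers fewer than 2 samples")
  fs <- 1000 / attr(trace, "dt_ms")
  dx <- diff(trace$x_smooth[idx]); dy <- diff(trace$y_smooth[idx])
  sp <- sqrt(dx^2 + dy^2) * fs * DEG_PER_PX
  data.frame(duration = offset_ms - onset_ms,
             amplitude = sqrt((trace$x_smooth[idx[length(idx)]] -
                                 trace$x_smooth[idx[1]])^2 +
                              (trace$y_smooth[idx[length(idx)]] -
                                 trace$y_smooth[idx[1]])^2) * DEG_PER_PX,
             peak_velocity = max(sp), mean_velocity = mean(sp))
}

#' Full oculomotor event detection
#'
#' Smooths the recording, estimates the adaptive velocity threshold (per
#' recording, so 30 s chunks with few saccades do not destabilize it),
#' classifies and merges fixation/saccade candidates, detects blinks, and
#' returns a single time-ordered event table.
#'
#' @param rec gaze recording (see [smooth_gaze()]).
#' @param window,polyorder Savitzky-Golay parameters.
#' @param init_threshold,tol adaptive-threshold settings (deg/s).
#' @param min_amp_deg,min_fix_ms merging floors.
#' @return event table of class `oc_events` with attribute `threshold`
#'   (deg/s).
#' @export
detect_events <- function(rec, window = 21L, polyorder = 2L,
                          init_threshold = 100, tol = 1,
                          min_amp_deg = 1.0, min_fix_ms = 60) {
  trace <- smooth_gaze(rec, window, polyorder)
  thr <- tryCatch(
    adaptive_velocity_threshold(trace, init_threshold, tol),
    error = function(e) {
      warning("adaptive threshold failed (", conditionMessage(e),
              "); falling back to the initial threshold")
      init_threshold
    })
  cand <- classify_candidates(trace, as.numeric(thr))
  ev <- merge_events(cand, min_amp_deg, min_fix_ms)
  blinks <- detect_blinks(rec)
  out <- rbind(as.data.frame(ev), as.data.frame(blinks))
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  structure(as_event_table(out), threshold = as.numeric(thr))
}
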