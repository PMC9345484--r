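## Session chunking, per-chunk heart rate, QC, and per-participant z-score
## binarization of heart rate into low/high labels.

#' Cut a session into fixed-length chunks with events and heart rate
#'
#' Windows are half-open `[start, end)` so events at boundaries are
#' unambiguous; events overlapping a window are clipped to it. The final
#' short window (if any) is kept in the table but marked unusable, as are
#' chunks whose gaze loss exceeds `max_gaze_loss` (fraction of the window
#' covered by no event at all) or whose heart-rate estimate fails quality
#' control.
#'
#' @param events event table from [detect_events()] (times in ms).
#' @param ppg PPG recording: data frame `time_s`, `value`.
#' @param chunk_s window length in seconds (default 30).
#' @param participant_id identifier attached to every chunk.
#' @param max_gaze_loss maximal tolerated gaze-loss fraction (default 0.5).
#' @return object of class `oc_chunks`: a list with `table` (one row per
#'   window: `participant`, `index`, `start_s`, `end_s`, `bpm`,
#'   `hr_quality`, `gaze_loss`, `usable`) and `events` (per-window clipped
#'   event tables).
#' @export
make_chunks <- function(events, ppg, chunk_s = 30, participant_id = "p1",
                        max_gaze_loss = 0.5) {
  stopifnot(chunk_s > 0)
  fs <- 1 / (ppg$time_s[2] - ppg$time_s[1])
  dur <- nrow(ppg) / fs
  if (dur <= chunk_s) stop("session shorter than one chunk")
  n_full <- floor(dur / chunk_s)
  has_rest <- dur - n_full * chunk_s > 1e-9
  n_win <- n_full + has_rest
  ev <- as.data.frame(events)

  rows <- vector("list", n_win)
  ev_lists <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    start <- (k - 1) * chunk_s
    end <- if (k <= n_full) start + chunk_s else dur
    sel <- ev$onset < end * 1000 & ev$offset > start * 1000
    evk <- ev[sel, , drop = FALSE]
    if (nrow(evk) > 0L) {
      evk$onset <- pmax(evk$onset, start * 1000)
      evk$offset <- pmin(evk$offset, end * 1000)
      evk$duration <- evk$offset - evk$onset
    }
    covered <- sum(evk$duration)
    loss <- min(max(1 - covered / ((end - start) * 1000), 0), 1)
    seg <- ppg[ppg$time_s >= start & ppg$time_s < end, , drop = FALSE]
    hr <- estimate_heart_rate(seg)
    rows[[k]] <- data.frame(
      participant = participant_id, index = k - 1L,
      start_s = start, end_s = end, bpm = hr$bpm,
      hr_quality = hr$quality_ok, gaze_loss = loss,
      usable = (k <= n_full) && loss <= max_gaze_loss && hr$quality_ok)
    ev_lists[[k]] <- as_event_table(evk)
  }
  structure(list(table = do.call(rbind, rows), events = ev_lists),
            class = "oc_chunks")
}

#' @export
print.oc_chunks <- function(x, ...) {
  cat("<oc_chunks>", nrow(x$table), "windows,", sum(x$table$usable),
      "usable\n")
  invisible(x)
}

#' Binarize chunk heart rates into low/high labels
#'
#' Each usable chunk's heart rate is expressed as a z-score: the number of
#' (sample) standard deviations from the participant's median heart rate
#' over the whole session. Chunks with `z < -threshold` are labeled `low`,
#' chunks with `z > threshold` are labeled `high`; all others are neutral
#' and dropped (strict inequalities, so `|z| == threshold` is neutral).
#'
#' @param chunks object from [make_chunks()].
#' @param z_threshold label threshold on |z| (default 0.5).
#' @return data frame `participant`, `index`, `bpm`, `z`, `label`
#'   (`"low"`/`"high"`), one row per labeled chunk. Empty (with a message)
#'   when the heart-rate SD is zero or fewer than 2 usable chunks exist.
#' @export
binarize_heart_rate <- function(chunks, z_threshold = 0.5) {
  tab <- chunks$table[chunks$table$usable, , drop = FALSE]
  empty <- data.frame(participant = character(0), index = integer(0),
                      bpm = numeric(0), z = numeric(0), label = character(0))
  if (nrow(tab) < 2L) {
    message("fewer than 2 usable chunks; no labels assigned")
    return(empty)
  }
  s <- sd(tab$bpm)
  if (!is.finite(s) || s == 0) {
    message("zero heart-rate variance; all chunks neutral")
    return(empty)
  }
  z <- (tab$bpm - median(tab$bpm)) / s
  label <- ifelse(z < -z_threshold, "low",
                  ifelse(z > z_threshold, "high", NA_character_))
  keep <- !is.na(label)
  data.frame(participant = tab$participant[keep], index = tab$index[keep],
             bpm = tab$bpm[keep], z = z[keep], label = label[keep])
}
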