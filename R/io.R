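## Readers and writers for the pipeline's delimited-text interfaces.
## Missing pupil samples round-trip both as the sentinel 0 and as NaN.

#' Read and write gaze recordings (TSV) and PPG recordings (CSV)
#'
#' Gaze files are tab-separated with columns `time_ms`, `x_px`, `y_px`,
#' `pupil`; PPG files are comma-separated with columns `time_s`, `value`.
#' On write, missing pupil samples are encoded as `NaN` (default) or the
#' sentinel `0`; on read, both encodings map back to missing.
#'
#' @param rec recording data frame.
#' @param path file path.
#' @param missing how to encode missing pupil samples: `"nan"` or `"zero"`.
#' @return `read_*` return the recording data frame; `write_*` return the
#'   path invisibly.
#' @export
write_gaze_tsv <- function(rec, path, missing = c("nan", "zero")) {
  missing <- match.arg(missing)
  out <- as.data.table(rec[c("time_ms", "x_px", "y_px", "pupil")])
  if (missing == "zero") out[is.na(pupil), pupil := 0]
  fwrite(out, path, sep = "\t", na = "NaN", quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_gaze_tsv <- function(path) {
  d <- as.data.frame(fread(path, sep = "\t",
                           na.strings = c("NA", "NaN", "nan")))
  stopifnot(all(c("time_ms", "x_px", "y_px", "pupil") %in% names(d)))
  d$pupil[!is.na(d$pupil) & d$pupil == 0] <- NA_real_
  d
}

#' @rdname write_gaze_tsv
#' @export
write_ppg_csv <- function(rec, path) {
  fwrite(as.data.table(rec[c("time_s", "value")]), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_ppg_csv <- function(path) {
  d <- as.data.frame(fread(path))
  stopifnot(all(c("time_s", "value") %in% names(d)))
  d
}

#' Write an event list as CSV
#'
#' Columns: `kind`, `onset_ms`, `offset_ms`, `duration_ms`, `amplitude_deg`,
#' `peak_vel_dps`, `mean_vel_dps`.
#'
#' @param events event table of class `oc_events`.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  ev <- as.data.frame(events)
  out <- data.frame(kind = ev$kind, onset_ms = ev$onset,
                    offset_ms = ev$offset, duration_ms = ev$duration,
                    amplitude_deg = ev$amplitude,
                    peak_vel_dps = ev$peak_velocity,
                    mean_vel_dps = ev$mean_velocity)
  fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  d <- as.data.frame(fread(path))
  as_event_table(data.frame(kind = d$kind, onset = d$onset_ms,
                            offset = d$offset_ms, duration = d$duration_ms,
                            amplitude = d$amplitude_deg,
                            peak_velocity = d$peak_vel_dps,
                            mean_velocity = d$mean_vel_dps))
}

#' Write simulation ground truth as JSON
#'
#' @param truth ground-truth list (`events`/`blinks` from [simulate_gaze()]
#'   or the heart-rate table from [simulate_ppg()]).
#' @param path file path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       na = "null")
  invisible(path)
}

## CSV with a provenance comment header; read back with comment.char = "#"
stamped_csv <- function(df, path, stamp) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
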