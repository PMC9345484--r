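## Shared fixture builders and independent oracles.

## evaluate code under a fixed seed without disturbing the outer RNG state
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

## a plain gaze recording at 1 kHz
make_recording <- function(x, y = rep(0, length(x)),
                           pupil = rep(1000, length(x))) {
  data.frame(time_ms = seq_along(x) - 1, x_px = x, y_px = y, pupil = pupil)
}

## a velocity trace built directly from a speed vector (bypassing smoothing)
make_trace <- function(speed, x = rep(0, length(speed)),
                       y = rep(0, length(speed)), dt_ms = 1) {
  structure(data.frame(time_ms = (seq_along(speed) - 1) * dt_ms,
                       x_smooth = x, y_smooth = y, speed = speed),
            dt_ms = dt_ms, class = c("oc_velocity", "data.frame"))
}

## random alternating fixation/saccade candidate sequences with consistent
## positions (saccade amplitude = endpoint displacement), for merge tests
random_candidates <- function(n_events, seed, n_segments = 1L) {
  set.seed(seed)
  n_segments <- min(n_segments, n_events)
  kind <- rep(c("fixation", "saccade"), length.out = n_events)
  if (runif(1) < 0.5) kind <- rev(kind)
  dur <- ifelse(kind == "fixation", round(runif(n_events, 20, 300)),
                round(runif(n_events, 10, 80)))
  onset <- cumsum(c(0, dur[-n_events]))
  px <- 500; py <- 500
  x_on <- y_on <- x_off <- y_off <- numeric(n_events)
  for (i in seq_len(n_events)) {
    x_on[i] <- px; y_on[i] <- py
    if (kind[i] == "saccade") {
      amp_px <- runif(1, 0.2, 3) / 0.0186
      ang <- runif(1, 0, 2 * pi)
      px <- px + amp_px * cos(ang); py <- py + amp_px * sin(ang)
    }
    x_off[i] <- px; y_off[i] <- py
  }
  seg_breaks <- if (n_segments > 1L)
    sort(sample(n_events - 1L, n_segments - 1L)) else integer(0)
  segment <- findInterval(seq_len(n_events) - 1L, seg_breaks)
  df <- data.frame(
    kind = kind, onset = onset, offset = onset + dur, duration = dur,
    amplitude = sqrt((x_off - x_on)^2 + (y_off - y_on)^2) * 0.0186,
    peak_velocity = NA, mean_velocity = NA,
    n_samples = dur, x_on = x_on, y_on = y_on, x_off = x_off,
    y_off = y_off, v_sum = runif(n_events, 1, 100) * dur,
    v_max = runif(n_events, 50, 500), segment = segment)
  df$peak_velocity <- df$v_max
  df$mean_velocity <- df$v_sum / df$n_samples
  class(df) <- c("oc_events", "data.frame")
  df
}

## deterministic alternating candidate chain with given kinds, durations
## (ms) and saccade amplitudes (deg); positions are consistent with the
## amplitudes (saccades move along x, fixations are still)
chain_candidates <- function(kind, dur, amp = rep(0, length(kind)),
                             segment = rep(0L, length(kind))) {
  n <- length(kind)
  onset <- cumsum(c(0, dur[-n]))
  x <- 500
  x_on <- x_off <- numeric(n)
  for (i in seq_len(n)) {
    x_on[i] <- x
    if (kind[i] == "saccade") x <- x + amp[i] / 0.0186
    x_off[i] <- x
  }
  df <- data.frame(kind = kind, onset = onset, offset = onset + dur,
                   duration = dur, amplitude = amp,
                   peak_velocity = 100, mean_velocity = 50,
                   n_samples = dur, x_on = x_on, y_on = 0,
                   x_off = x_off, y_off = 0, v_sum = 50 * dur, v_max = 100,
                   segment = segment)
  class(df) <- c("oc_events", "data.frame")
  df
}

## Brute-force merging oracle: repeatedly find the FIRST offending event and
## dissolve it into its immediate neighbours (same segment only), one event
## at a time; pass 1 (small saccades) runs to completion before pass 2
## (short fixations). Structurally independent of the vectorized
## implementation.
naive_merge <- function(ev, min_amp = 1, min_fix = 60) {
  ev <- as.data.frame(ev)
  fuse <- function(block, kind, amp_rule) {
    nb <- nrow(block)
    amp <- if (amp_rule == "displacement") {
      sqrt((block$x_off[nb] - block$x_on[1])^2 +
             (block$y_off[nb] - block$y_on[1])^2) * 0.0186
    } else sum(block$amplitude[block$kind == "saccade"])
    data.frame(kind = kind, onset = block$onset[1],
               offset = block$offset[nb],
               duration = block$offset[nb] - block$onset[1],
               amplitude = amp, peak_velocity = max(block$v_max),
               mean_velocity = sum(block$v_sum) / sum(block$n_samples),
               n_samples = sum(block$n_samples),
               x_on = block$x_on[1], y_on = block$y_on[1],
               x_off = block$x_off[nb], y_off = block$y_off[nb],
               v_sum = sum(block$v_sum), v_max = max(block$v_max),
               segment = block$segment[1])
  }
  one_pass <- function(ev, offender, absorber, amp_rule) {
    repeat {
      bad <- offender(ev)
      i <- which(bad)[1]
      if (is.na(i)) break
      lo <- i; hi <- i
      if (i > 1 && ev$segment[i - 1] == ev$segment[i] &&
            ev$kind[i - 1] == absorber) lo <- i - 1
      if (i < nrow(ev) && ev$segment[i + 1] == ev$segment[i] &&
            ev$kind[i + 1] == absorber) hi <- i + 1
      if (lo == hi) { ev <- ev[-i, , drop = FALSE]; next }
      merged <- fuse(ev[lo:hi, , drop = FALSE], absorber, amp_rule)
      ev <- rbind(if (lo > 1) ev[1:(lo - 1), , drop = FALSE],
                  merged,
                  if (hi < nrow(ev)) ev[(hi + 1):nrow(ev), , drop = FALSE])
      rownames(ev) <- NULL
    }
    ev
  }
  ev <- one_pass(ev, function(e) e$kind == "saccade" & e$amplitude < min_amp,
                 "fixation", "displacement")
  ev <- one_pass(ev, function(e) e$kind == "fixation" & e$duration < min_fix,
                 "saccade", "sum")
  rownames(ev) <- NULL
  ev
}

## Independent heart-rate oracle: the beat period is the smallest
## autocorrelation lag in the physiological band whose correlation comes
## close to the band maximum (robust against harmonics, unlike a raw
## Fourier peak). Shares no code path with the time-domain peak detector.
acf_hr_oracle <- function(segment) {
  fs <- 1 / (segment$time_s[2] - segment$time_s[1])
  x <- segment$value - mean(segment$value)
  lag_max <- floor(1.5 * fs)            # 40 bpm
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  lags <- seq_along(ac) / fs
  band <- lags >= 60 / 180 & lags <= 60 / 40
  cand <- which(band & ac >= 0.8 * max(ac[band]))
  ## hill-climb to the local maximum, then refine the lag by parabolic
  ## interpolation (the 10 ms lag grid is otherwise too coarse at high bpm)
  k <- cand[1]
  while (k < length(ac) && ac[k + 1] > ac[k]) k <- k + 1
  while (k > 1 && ac[k - 1] > ac[k]) k <- k - 1
  delta <- if (k > 1 && k < length(ac)) {
    0.5 * (ac[k - 1] - ac[k + 1]) /
      (ac[k - 1] - 2 * ac[k] + ac[k + 1])
  } else 0
  60 * fs / (k + delta)
}

## base feature sets built directly from value lists (bypassing detection)
fake_set <- function(fix_dur = numeric(0), sac_dur = numeric(0),
                     blink_dur = numeric(0), fix_amp = numeric(0),
                     sac_amp = numeric(0), fix_pv = numeric(0),
                     sac_pv = numeric(0), fix_mv = numeric(0),
                     sac_mv = numeric(0)) {
  structure(list(
    fixation_duration = fix_dur, saccade_duration = sac_dur,
    blink_duration = blink_dur, fixation_amplitude = fix_amp,
    saccade_amplitude = sac_amp, fixation_peak_velocity = fix_pv,
    saccade_peak_velocity = sac_pv, fixation_mean_velocity = fix_mv,
    saccade_mean_velocity = sac_mv, fixation_count = length(fix_dur),
    saccade_count = length(sac_dur), blink_count = length(blink_dur)),
    class = "oc_basefeatures")
}

random_set <- function(seed) {
  set.seed(seed)
  nf <- sample(0:30, 1); ns <- sample(0:30, 1); nb <- sample(0:5, 1)
  fake_set(fix_dur = runif(nf, 60, 500), sac_dur = runif(ns, 15, 80),
           blink_dur = runif(nb, 50, 400), fix_amp = runif(nf, 0, 1),
           sac_amp = runif(ns, 1, 8), fix_pv = runif(nf, 1, 10),
           sac_pv = runif(ns, 80, 400), fix_mv = runif(nf, 0.5, 4),
           sac_mv = runif(ns, 40, 200))
}

## arousal trace pinned to a constant level
constant_arousal <- function(level, duration_s) {
  data.frame(time = seq_len(max(2, ceiling(duration_s))) - 1, level = level)
}
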