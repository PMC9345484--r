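## Synthetic arousal-coupled gaze + pulse-oximetry sessions.
##
## A latent, slowly fluctuating arousal level jointly modulates heart rate and
## oculomotor behaviour (blink rate, saccadic velocity/amplitude, fixational
## drift). The generator returns ground truth for every event and for the
## instantaneous heart rate, so each downstream stage of the pipeline can be
## validated without external recordings.

SCREEN_W <- 1280
SCREEN_H <- 1024
SCREEN_MARGIN <- 50

#' Simulation configuration
#'
#' All arousal effects are scaled by a single `coupling` knob in `[0, 1]`:
#' `coupling = 0` makes the generated gaze statistics independent of heart
#' rate. Modulated quantities follow
#' `base * (1 + coupling * gain * (arousal - 0.5))` except the blink rate,
#' which is `blink_rate_base + coupling * blink_rate_gain * arousal`
#' (events/min), and the heart rate, which is
#' `base_hr + coupling * hr_gain * arousal` plus slow arousal-independent
#' variability of SD `hr_noise_sd` bpm.
#'
#' @param duration_s session length in seconds (default 7200, a 2 h film).
#' @param gaze_hz gaze sampling rate in Hz (default 1000).
#' @param ppg_hz pulse-oximetry sampling rate in Hz (default 100).
#' @param base_hr baseline heart rate, bpm.
#' @param hr_gain heart-rate gain, bpm per unit arousal.
#' @param hr_noise_sd SD (bpm) of slow heart-rate variability independent of
#'   arousal (time constant 30 s).
#' @param blink_rate_base,blink_rate_gain blink rate intercept and arousal
#'   gain, events/min.
#' @param saccade_rate saccade rate, events/s; fixation durations are
#'   log-normal with median `0.3 * 3 / saccade_rate` seconds, so the default
#'   rate of 3/s gives the canonical ~300 ms fixations of free viewing.
#' @param main_seq_slope main-sequence slope: saccadic peak velocity is
#'   `main_seq_slope * amplitude` (deg/s per deg).
#' @param amp_median_deg,amp_sdlog log-normal saccade amplitude parameters.
#' @param vel_gain,amp_gain,drift_gain fractional arousal modulation of the
#'   main-sequence slope, saccade amplitude and fixational drift.
#' @param drift_sd fixational drift velocity SD, deg/s.
#' @param noise_sd_deg white measurement noise SD on gaze position, degrees.
#' @param ppg_noise_sd additive white noise SD on the PPG waveform
#'   (systolic peak amplitude is 1).
#' @param coupling dimensionless in `[0, 1]`, scales all arousal effects.
#' @param seed integer master seed; the sub-generators use `seed`, `seed + 1`,
#'   `seed + 2` so the three signals are reproducible yet independent.
#' @return an object of class `oc_sim_config` (a validated list).
#' @export
sim_config <- function(duration_s = 7200, gaze_hz = 1000, ppg_hz = 100,
                       base_hr = 70, hr_gain = 20, hr_noise_sd = 2,
                       blink_rate_base = 5, blink_rate_gain = 20,
                       saccade_rate = 3, main_seq_slope = 50,
                       amp_median_deg = 4, amp_sdlog = 0.6,
                       vel_gain = 0.3, amp_gain = 0.2, drift_gain = 0.3,
                       drift_sd = 0.5, noise_sd_deg = 0.005,
                       ppg_noise_sd = 0.05, coupling = 1, seed = 1L) {
  cfg <- as.list(environment())
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0)
    stop("`duration_s` must be positive")
  rates <- c("gaze_hz", "ppg_hz", "hr_gain", "hr_noise_sd", "blink_rate_base",
             "blink_rate_gain", "saccade_rate", "main_seq_slope",
             "amp_median_deg", "amp_sdlog", "vel_gain", "amp_gain",
             "drift_gain", "drift_sd", "noise_sd_deg", "ppg_noise_sd")
  for (nm in rates)
    if (cfg[[nm]] < 0) stop("`", nm, "` must be non-negative")
  if (cfg$coupling < 0 || cfg$coupling > 1)
    stop("`coupling` must be in [0, 1]")
  if (cfg$base_hr < 40 || cfg$base_hr + cfg$hr_gain > 180)
    stop("`base_hr` + `hr_gain` must stay within [40, 180] bpm")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "oc_sim_config")
}

#' @export
print.oc_sim_config <- function(x, ...) {
  cat("<oc_sim_config>", x$duration_s, "s,", x$gaze_hz, "Hz gaze /",
      x$ppg_hz, "Hz PPG, coupling", x$coupling, ", seed", x$seed, "\n")
  invisible(x)
}

#' Simulate the latent arousal trace
#'
#' A mean-reverting (Ornstein-Uhlenbeck) process at 1 Hz with time constant
#' 120 s, stationary mean 0.5 and SD 0.15, clamped to `[0, 1]`. The slow time
#' constant makes arousal roughly constant within a 30 s analysis chunk.
#'
#' @param config an [sim_config()] object.
#' @return data frame with columns `time` (s) and `level` (dimensionless,
#'   bounded in `[0, 1]`).
#' @export
simulate_arousal <- function(config) {
  stopifnot(inherits(config, "oc_sim_config"))
  if (config$duration_s <= 0) stop("`duration_s` must be positive")
  n <- max(2L, ceiling(config$duration_s))
  tau <- 120; mu <- 0.5; marg_sd <- 0.15
  alpha <- exp(-1 / tau)
  innov_sd <- marg_sd * sqrt(1 - alpha^2)
  with_seed(config$seed, {
    a0 <- rnorm(1, mu, marg_sd)
    eps <- rnorm(n - 1L, 0, innov_sd)
    dev <- as.numeric(stats::filter(eps, alpha, method = "recursive",
                                    init = a0 - mu))
    level <- pmin(pmax(mu + c(a0 - mu, dev), 0), 1)
    data.frame(time = seq_len(n) - 1, level = level)
  })
}

## linear interpolant of the arousal trace, constant beyond its range
arousal_fun <- function(arousal) {
  if (nrow(arousal) < 1L) stop("empty arousal trace")
  approxfun(arousal$time, arousal$level, rule = 2)
}

## raised-cosine bump with separate left/right half-widths (asymmetric)
cos_bump <- function(u, center, wl, wr) {
  d <- u - center
  out <- numeric(length(u))
  i <- d > -wl & d < 0
  out[i] <- 0.5 * (1 + cos(pi * d[i] / wl))
  i <- d >= 0 & d < wr
  out[i] <- 0.5 * (1 + cos(pi * d[i] / wr))
  out
}

## one cardiac cycle as a function of phase in [0, 1): asymmetric systolic
## peak (amplitude 1 at phase 0.18) plus a smaller dicrotic bump
pulse_shape <- function(u) {
  cos_bump(u, 0.18, 0.10, 0.22) + 0.35 * cos_bump(u, 0.55, 0.12, 0.15)
}

#' Simulate a gaze recording with ground-truth events
#'
#' Alternating fixations (log-normal durations, OU fixational drift) and
#' saccades obeying a main-sequence amplitude-velocity relation, plus blinks
#' from an inhomogeneous Poisson process that set the pupil channel to
#' missing. Saccade trajectories use a peaked symmetric velocity profile
#' `v(u) ~ (1 - |2u - 1|)^q` whose exponent is chosen per saccade so the peak
#' velocity matches the (arousal-modulated) main-sequence target while the
#' duration follows the amplitude-only rule `2.2 * amplitude + 21` ms; this
#' keeps saccade durations uncoupled from velocity modulation.
#'
#' @param arousal arousal trace from [simulate_arousal()].
#' @param config an [sim_config()] object.
#' @return list with `recording` (data frame `time_ms`, `x_px`, `y_px`,
#'   `pupil`; pupil is `NA` during blinks) and `truth` (list of `events` and
#'   `blinks` data frames, onsets/offsets in seconds).
#' @export
simulate_gaze <- function(arousal, config) {
  stopifnot(inherits(config, "oc_sim_config"))
  if (nrow(arousal) < 1L) stop("empty arousal trace")
  if (max(arousal$time) < config$duration_s - 1)
    stop("arousal trace does not cover the full duration")
  a_fun <- arousal_fun(arousal)
  fs <- config$gaze_hz
  dur <- config$duration_s
  n <- round(dur * fs)
  cpl <- config$coupling

  with_seed(config$seed + 1L, {
    sched <- schedule_oculomotor_events(a_fun, config)
    ## --- sample-level trajectory -------------------------------------
    ev <- sched$timeline  # interleaved fixation/saccade timeline
    start_idx <- pmin(floor(ev$onset * fs), n - 1L) + 1L
    lens <- diff(c(start_idx, n + 1L))
    x <- rep(ev$x0, times = lens)
    y <- rep(ev$y0, times = lens)
    sac <- which(ev$kind == "saccade" & lens > 0L)
    for (k in sac) {
      m <- lens[k]
      i0 <- start_idx[k]
      u <- (seq_len(m) - 0.5) / m
      w <- (1 - abs(2 * u - 1))^ev$q[k]
      cw <- cumsum(w) / sum(w)
      x[i0:(i0 + m - 1L)] <- ev$x0[k] + (ev$x1[k] - ev$x0[k]) * cw
      y[i0:(i0 + m - 1L)] <- ev$y0[k] + (ev$y1[k] - ev$y0[k]) * cw
    }
    ## --- fixational drift + measurement noise ------------------------
    t_samp <- (seq_len(n) - 1) / fs
    if (config$drift_sd > 0) {
      dscale <- 1 + cpl * config$drift_gain * (a_fun(t_samp) - 0.5)
      step_px <- config$drift_sd / fs / DEG_PER_PX
      alpha_d <- exp(-1 / (0.05 * fs))
      x <- x + as.numeric(stats::filter(rnorm(n, 0, step_px) * dscale,
                                        alpha_d, method = "recursive"))
      y <- y + as.numeric(stats::filter(rnorm(n, 0, step_px) * dscale,
                                        alpha_d, method = "recursive"))
    }
    if (config$noise_sd_deg > 0) {
      noise_px <- config$noise_sd_deg / DEG_PER_PX
      x <- x + rnorm(n, 0, noise_px)
      y <- y + rnorm(n, 0, noise_px)
    }
    ## --- pupil channel with blink gaps -------------------------------
    pupil <- 1100 +
      as.numeric(stats::filter(rnorm(n, 0, 30 * sqrt(1 - exp(-2 / (60 * fs)))),
                               exp(-1 / (60 * fs)), method = "recursive")) +
      rnorm(n, 0, 5)
    blinks <- draw_blinks(a_fun, config)
    if (nrow(blinks) > 0L) {
      for (k in seq_len(nrow(blinks))) {
        i0 <- max(1L, floor(blinks$onset[k] * fs) + 1L)
        i1 <- min(n, ceiling(blinks$offset[k] * fs))
        pupil[i0:i1] <- NA_real_
      }
    }
    recording <- data.frame(time_ms = (seq_len(n) - 1) * 1000 / fs,
                            x_px = x, y_px = y, pupil = pupil)
    list(recording = recording,
         truth = list(events = sched$events, blinks = blinks))
  })
}

## Sequentially draw the fixation/saccade schedule. Returns the ground-truth
## event table and a sample-filling timeline with per-event endpoints.
schedule_oculomotor_events <- function(a_fun, config) {
  dur <- config$duration_s
  cpl <- config$coupling
  lo_x <- SCREEN_MARGIN; hi_x <- SCREEN_W - SCREEN_MARGIN
  lo_y <- SCREEN_MARGIN; hi_y <- SCREEN_H - SCREEN_MARGIN
  px <- SCREEN_W / 2; py <- SCREEN_H / 2

  cap <- max(16L, ceiling(dur * max(config$saccade_rate, 0.1) * 2))
  kind <- character(cap); onset <- offset <- numeric(cap)
  x0 <- y0 <- x1 <- y1 <- qv <- amp <- pv <- numeric(cap)
  m <- 0L
  push <- function(k, on, off, ax0, ay0, ax1, ay1, q = NA, a = NA, p = NA) {
    m <<- m + 1L
    if (m > length(kind)) { # grow
      grow <- function(v) c(v, vector(mode = mode(v), length = length(v)))
      kind <<- grow(kind); onset <<- grow(onset); offset <<- grow(offset)
      x0 <<- grow(x0); y0 <<- grow(y0); x1 <<- grow(x1); y1 <<- grow(y1)
      qv <<- grow(qv); amp <<- grow(amp); pv <<- grow(pv)
    }
    kind[m] <<- k; onset[m] <<- on; offset[m] <<- off
    x0[m] <<- ax0; y0[m] <<- ay0; x1[m] <<- ax1; y1[m] <<- ay1
    qv[m] <<- q; amp[m] <<- a; pv[m] <<- p
  }

  if (config$saccade_rate <= 0) {
    push("fixation", 0, dur, px, py, px, py)
  } else {
    fix_meanlog <- log(0.3 * 3 / config$saccade_rate)
    t <- 0
    repeat {
      fdur <- rlnorm(1, fix_meanlog, 0.4)
      if (t + fdur >= dur) { push("fixation", t, dur, px, py, px, py); break }
      t2 <- t + fdur
      a2 <- a_fun(t2)
      amp_deg <- rlnorm(1, log(config$amp_median_deg *
                               (1 + cpl * config$amp_gain * (a2 - 0.5))),
                        config$amp_sdlog)
      amp_deg <- min(amp_deg, 18)
      slope <- config$main_seq_slope *
        (1 + cpl * config$vel_gain * (a2 - 0.5))
      pv_target <- slope * amp_deg * exp(rnorm(1, 0, 0.05))
      D <- (2.2 * amp_deg + 21) / 1000 * exp(rnorm(1, 0, 0.1))
      q <- max(pv_target * D / amp_deg - 1, 0.05)
      if (t2 + D >= dur) { push("fixation", t, dur, px, py, px, py); break }
      amp_px <- amp_deg / DEG_PER_PX
      for (try in 1:25) {
        ang <- runif(1, 0, 2 * pi)
        tx <- px + amp_px * cos(ang); ty <- py + amp_px * sin(ang)
        if (tx >= lo_x && tx <= hi_x && ty >= lo_y && ty <= hi_y) break
        if (try == 25) { # point straight at screen center
          ang <- atan2(SCREEN_H / 2 - py, SCREEN_W / 2 - px)
          tx <- px + amp_px * cos(ang); ty <- py + amp_px * sin(ang)
          tx <- min(max(tx, lo_x), hi_x); ty <- min(max(ty, lo_y), hi_y)
        }
      }
      push("fixation", t, t2, px, py, px, py)
      push("saccade", t2, t2 + D, px, py, tx, ty, q = q, a = amp_deg,
           p = (q + 1) * amp_deg / D)
      px <- tx; py <- ty
      t <- t2 + D
    }
  }
  idx <- seq_len(m)
  timeline <- data.frame(kind = kind[idx], onset = onset[idx],
                         offset = offset[idx], x0 = x0[idx], y0 = y0[idx],
                         x1 = x1[idx], y1 = y1[idx], q = qv[idx])
  events <- data.frame(kind = kind[idx], onset = onset[idx],
                       offset = offset[idx], amplitude_deg = amp[idx],
                       peak_velocity = pv[idx])
  list(timeline = timeline, events = events)
}

## Inhomogeneous Poisson blink onsets (thinning) with log-normal durations
## (median 150 ms, clipped to [50, 1000] ms). Blinks that overlap or almost
## touch (< 5 ms apart, below the detector's resolution) are unioned into
## one, so the ground-truth count matches what any gap-based detector can
## resolve; the union loses < ~3 percent of events at default rates, well
## inside the Poisson band.
draw_blinks <- function(a_fun, config) {
  dur <- config$duration_s
  rate_s <- function(t)
    (config$blink_rate_base +
       config$coupling * config$blink_rate_gain * a_fun(t)) / 60
  if (config$blink_rate_base + config$blink_rate_gain <= 0)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  grid <- seq(0, dur, length.out = 512)
  rmax <- max(rate_s(grid))
  if (rmax <= 0) return(data.frame(onset = numeric(0), offset = numeric(0)))
  n_cand <- rpois(1, rmax * dur)
  cand <- sort(runif(n_cand, 0, dur))
  keep <- cand[runif(n_cand) < rate_s(cand) / rmax]
  durs <- pmin(pmax(rlnorm(length(keep), log(0.15), 0.3), 0.05), 1.0)
  ok <- keep + durs < dur
  keep <- keep[ok]; durs <- durs[ok]
  if (length(keep) == 0L)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  onset <- numeric(length(keep)); offset <- numeric(length(keep))
  k <- 1L
  onset[1] <- keep[1]; offset[1] <- keep[1] + durs[1]
  for (i in seq_along(keep)[-1]) {
    if (keep[i] <= offset[k] + 0.005) { # union with the previous blink
      offset[k] <- max(offset[k], keep[i] + durs[i])
    } else {
      k <- k + 1L
      onset[k] <- keep[i]; offset[k] <- keep[i] + durs[i]
    }
  }
  data.frame(onset = onset[seq_len(k)], offset = offset[seq_len(k)])
}

#' Simulate a pulse-oximetry (PPG) recording
#'
#' Repeated asymmetric pulse waveforms (raised-cosine systolic peak plus a
#' smaller dicrotic bump) at instantaneous rate
#' `base_hr + coupling * hr_gain * arousal + slow noise`, sampled at
#' `ppg_hz`, with additive white measurement noise. The true per-second heart
#' rate is returned as ground truth.
#'
#' @inheritParams simulate_gaze
#' @return list with `recording` (data frame `time_s`, `value`) and `truth`
#'   (data frame `time_s`, `hr_bpm`).
#' @export
simulate_ppg <- function(arousal, config) {
  stopifnot(inherits(config, "oc_sim_config"))
  if (nrow(arousal) < 1L) stop("empty arousal trace")
  if (config$base_hr < 40 || config$base_hr + config$hr_gain > 180)
    stop("`base_hr` + `hr_gain` must stay within [40, 180] bpm")
  a_fun <- arousal_fun(arousal)
  fs <- config$ppg_hz
  dur <- config$duration_s
  n <- round(dur * fs)
  with_seed(config$seed + 2L, {
    t <- (seq_len(n) - 1) / fs
    r <- config$base_hr + config$coupling * config$hr_gain * a_fun(t)
    if (config$hr_noise_sd > 0) {
      alpha <- exp(-1 / (30 * fs))
      innov <- config$hr_noise_sd * sqrt(1 - alpha^2)
      r <- r + as.numeric(stats::filter(rnorm(n, 0, innov), alpha,
                                        method = "recursive"))
    }
    r <- pmin(pmax(r, 40), 180)
    phase <- cumsum(r / 60) / fs
    value <- pulse_shape(phase %% 1)
    if (config$ppg_noise_sd > 0) value <- value + rnorm(n, 0, config$ppg_noise_sd)
    sec <- 0:(floor(dur) - 1)
    truth <- data.frame(time_s = sec, hr_bpm = r[pmin(sec * fs + 1, n)])
    list(recording = data.frame(time_s = t, value = value), truth = truth)
  })
}

#' Derive a participant-specific configuration
#'
#' Real cohorts show large, stable inter-individual differences in
#' oculomotor baselines (spontaneous blink rates span an order of magnitude
#' across healthy adults) and in resting heart rate. When several simulated
#' participants are pooled -- as the modeling stage does -- this
#' heterogeneity is what distinguishes a per-participant-normalized label
#' from a pooled feature level, so it must be part of the stated world.
#' Multiplicative log-normal jitter is applied to the oculomotor baselines
#' (blink rate sdlog 0.6, saccade rate 0.2, main-sequence slope 0.15,
#' amplitude 0.25, drift 0.3) and Gaussian jitter (SD 7 bpm, clamped to
#' 45-110) to the baseline heart rate. The jitter is seeded by
#' `config$seed + participant` and the returned config's own seed is offset
#' per participant, so multi-participant experiments are reproducible.
#'
#' @param config base [sim_config()].
#' @param participant positive integer participant index.
#' @return a new `oc_sim_config` for this participant.
#' @export
participant_config <- function(config, participant) {
  stopifnot(inherits(config, "oc_sim_config"), participant >= 1)
  with_seed(config$seed + as.integer(participant), {
    cfg <- config
    cfg$blink_rate_base <- config$blink_rate_base * exp(rnorm(1, 0, 0.6))
    cfg$saccade_rate <- config$saccade_rate * exp(rnorm(1, 0, 0.2))
    cfg$main_seq_slope <- config$main_seq_slope * exp(rnorm(1, 0, 0.15))
    cfg$amp_median_deg <- config$amp_median_deg * exp(rnorm(1, 0, 0.25))
    cfg$drift_sd <- config$drift_sd * exp(rnorm(1, 0, 0.3))
    cfg$base_hr <- min(max(config$base_hr + rnorm(1, 0, 7), 45),
                       110)
    cfg$seed <- config$seed + 100L * as.integer(participant)
    cfg
  })
}

#' Simulate a full session (arousal + gaze + PPG)
#'
#' @param config an [sim_config()] object.
#' @return list with `arousal`, `gaze` (see [simulate_gaze()]) and `ppg`
#'   (see [simulate_ppg()]).
#' @export
simulate_session <- function(config) {
  arousal <- simulate_arousal(config)
  list(arousal = arousal,
       gaze = simulate_gaze(arousal, config),
       ppg = simulate_ppg(arousal, config))
}
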