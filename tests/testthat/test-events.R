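## Oculomotor event classification: smoothing, adaptive threshold,
## candidate classification, merging criteria, blinks, metrics.

test_that("smoothing: stillness gives zero speed, a linear ramp the exact
           closed-form speed, and a step the exact displacement", {
  still <- smooth_gaze(make_recording(rep(10, 500), rep(-3, 500)))
  expect_equal(still$speed, rep(0, 500), tolerance = 1e-12)

  ## x(t) = t px at 1 kHz: a polynomial filter reproduces a linear signal
  ## exactly (including the fitted edges), so speed = 1000 * 0.0186 deg/s
  ramp <- smooth_gaze(make_recording(0:999))
  expect_equal(ramp$speed, rep(18.6, 1000), tolerance = 1e-9)

  step <- smooth_gaze(make_recording(c(rep(0, 300), rep(100, 300))))
  d_px <- mean(step$x_smooth[451:600]) - mean(step$x_smooth[1:150])
  expect_equal(d_px * 0.0186, 1.86, tolerance = 1e-6)
  expect_equal(px_to_deg(100), 1.86)
  expect_equal(deg_to_px(px_to_deg(123.456)), 123.456, tolerance = 1e-9)
})

test_that("smoothing respects gaps: speed is missing where pupil is missing
           (0 or NaN) and short segments pass through", {
  pupil <- rep(1000, 400)
  pupil[101:200] <- NA  # a gap
  pupil[301:310] <- 0   # sentinel encoding, second (short) segment split
  rec <- make_recording(seq(0, 399) * 0.5, pupil = pupil)
  tr <- suppressMessages(smooth_gaze(rec))
  expect_true(all(is.na(tr$speed[101:200])))
  expect_true(all(is.na(tr$speed[301:310])))
  expect_true(all(is.finite(tr$speed[1:100])))
  ## the 10-sample tail segment is shorter than the window: passes through
  expect_message(smooth_gaze(make_recording(rnorm(10))), "unsmoothed")
})

test_that("adaptive threshold: degenerate one-step convergence and
           fixed-point oracle equivalence on bimodal speeds", {
  tr <- make_trace(rep(5, 200))
  expect_equal(as.numeric(adaptive_velocity_threshold(tr, 100)), 5)

  ## oracle: direct fixed-point iteration, written independently
  oracle_threshold <- function(s, init = 100, tol = 1) {
    thr <- init
    repeat {
      b <- s[s < thr]
      if (!length(b)) return(thr)
      nxt <- mean(b) + 6 * (if (length(b) > 1) sd(b) else 0)
      if (abs(nxt - thr) < tol) return(nxt)
      thr <- nxt
    }
  }
  for (seed in 1:50) {
    set.seed(seed)
    s <- c(abs(rnorm(2000, 10, 2)), rnorm(150, 300, 50))
    thr <- as.numeric(adaptive_velocity_threshold(make_trace(s), 100))
    expect_equal(thr, oracle_threshold(s), tolerance = 1e-9)
    expect_gt(thr, 10)   # strictly between the two mode means
    expect_lt(thr, 300)
  }
})

test_that("adaptive threshold error contract: nothing below the initial
           threshold falls back (with a warning)", {
  tr <- make_trace(rep(500, 200))
  expect_warning(thr <- adaptive_velocity_threshold(tr, init_threshold = 100),
                 "no speeds below")
  expect_equal(as.numeric(thr), 100)
})

test_that("candidate classification: runs below/above threshold, truncation
           at gaps, and run-length oracle equivalence", {
  ## all slow -> one fixation spanning the trace
  one <- classify_candidates(make_trace(rep(3, 250)), 30)
  expect_equal(nrow(one), 1L)
  expect_equal(one$kind, "fixation")
  expect_equal(c(one$onset, one$offset), c(0, 250))

  ## low x100, high x20, low x100 -> fixation, saccade, fixation
  s <- c(rep(5, 100), rep(200, 20), rep(5, 100))
  ev <- classify_candidates(make_trace(s), 30)
  expect_equal(ev$kind, c("fixation", "saccade", "fixation"))
  expect_equal(ev$n_samples, c(100, 20, 100))
  ## brute-force run-length oracle over random speed vectors
  for (seed in 1:20) {
    set.seed(seed)
    sp <- sample(c(5, 200), 400, replace = TRUE, prob = c(0.9, 0.1))
    got <- classify_candidates(make_trace(sp), 30)
    runs <- rle(sp >= 30)
    expect_equal(got$kind, ifelse(runs$values, "saccade", "fixation"))
    expect_equal(got$n_samples, as.numeric(runs$lengths))
  }

  ## a mid-trace gap: candidates do not span it, segments differ
  sp <- rep(5, 300); sp[121:180] <- NA
  ev <- classify_candidates(make_trace(sp), 30)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$offset[1], 120)
  expect_equal(ev$onset[2], 180)
  expect_true(ev$segment[1] != ev$segment[2])

  expect_equal(nrow(classify_candidates(make_trace(numeric(0)), 30)), 0L)
  expect_error(classify_candidates(make_trace(rep(1, 10)), 0), "positive")
})

test_that("merging criteria: amplitude floor (strict <) and duration floor
           (strict <) behave at the boundary", {
  ## a 0.9 deg saccade between two fixations -> one merged fixation
  cand <- chain_candidates(c("fixation", "saccade", "fixation"),
                           dur = c(150, 30, 200), amp = c(0, 0.9, 0))
  merged <- merge_events(cand)
  expect_equal(merged$kind, "fixation")
  expect_equal(merged$onset, cand$onset[1])
  expect_equal(merged$offset, cand$offset[3])
  ## amplitude recomputed from the merged span's endpoints (0.9 deg of
  ## net displacement remains across the dissolved saccade)
  expect_equal(merged$amplitude, 0.9, tolerance = 1e-12)

  ## exactly 1.0 deg is kept (strict <)
  cand2 <- chain_candidates(c("fixation", "saccade", "fixation"),
                            dur = c(150, 30, 200), amp = c(0, 1.0, 0))
  expect_equal(nrow(merge_events(cand2)), 3L)

  ## 59 ms fixation removed, 60 ms kept
  for (d in c(59, 60)) {
    tri <- chain_candidates(c("saccade", "fixation", "saccade"),
                            dur = c(40, d, 50), amp = c(2, 0, 3))
    out <- merge_events(tri)
    if (d < 60) {
      expect_equal(out$kind, "saccade")
      expect_equal(out$amplitude, 2 + 3) # sum rule for merged saccades
      expect_equal(out$duration, 40 + d + 50)
    } else {
      expect_equal(nrow(out), 3L)
    }
  }
})

test_that("merging equals the brute-force repeated-scan oracle on 200
           random candidate sequences and satisfies the floors", {
  for (seed in 1:200) {
    n <- sample(2:20, 1)
    cand <- random_candidates(n, seed = seed,
                              n_segments = sample(1:3, 1))
    got <- as.data.frame(merge_events(cand))
    want <- naive_merge(cand)
    expect_equal(got, want, tolerance = 1e-12)
    ## post-merge floors and per-segment alternation
    expect_true(all(got$amplitude[got$kind == "saccade"] >= 1.0))
    expect_true(all(got$duration[got$kind == "fixation"] >= 60))
    same_seg <- diff(got$segment) == 0
    expect_true(all(got$kind[-1][same_seg] != got$kind[-nrow(got)][same_seg]))
  }
  expect_equal(nrow(merge_events(classify_candidates(
    make_trace(numeric(0)), 30))), 0L)
})

test_that("blink detection keeps gaps in [30, 3000] ms inclusive and maps
           both missing encodings", {
  pupil <- rep(1000, 8000)
  gaps <- list(c(101, 110), c(301, 350), c(1001, 1200), c(2001, 6000))
  for (g in gaps) pupil[g[1]:g[2]] <- NA
  bl <- detect_blinks(make_recording(rnorm(8000), pupil = pupil))
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$duration, c(50, 200))

  ## exact boundaries kept: 30 ms and 3000 ms
  pupil <- rep(1000, 8000)
  pupil[101:130] <- 0          # 30 ms, sentinel encoding
  pupil[1001:4000] <- NA       # 3000 ms
  bl <- detect_blinks(make_recording(rnorm(8000), pupil = pupil))
  expect_equal(bl$duration, c(30, 3000))
  expect_equal(bl$kind, c("blink", "blink"))

  ## 29 ms and 3001 ms are data loss, not blinks
  pupil <- rep(1000, 8000)
  pupil[101:129] <- NA
  pupil[1001:4001] <- NA
  expect_equal(nrow(detect_blinks(make_recording(rnorm(8000),
                                                 pupil = pupil))), 0L)

  expect_equal(nrow(detect_blinks(make_recording(rnorm(100)))), 0L)
})

test_that("event metrics: hand-computed values and peak >= mean", {
  ## still 100 ms span
  tr <- smooth_gaze(make_recording(rep(50, 400)))
  m <- event_metrics(100, 200, tr)
  expect_equal(m$duration, 100)
  expect_equal(m$amplitude, 0, tolerance = 1e-12)
  expect_equal(m$peak_velocity, 0, tolerance = 1e-12)

  ## linear 100 px sweep over 50 ms (2 px/ms ramp, smoothing is exact on a
  ## linear signal): amplitude 1.86 deg, mean velocity 37.2 deg/s
  tr <- smooth_gaze(make_recording(2 * (0:300)))
  m <- event_metrics(100, 150, tr)
  expect_equal(m$amplitude, 1.86, tolerance = 1e-6)
  expect_equal(m$mean_velocity, 37.2, tolerance = 1e-6)

  ## peak >= mean on arbitrary spans
  set.seed(9)
  tr <- smooth_gaze(make_recording(cumsum(rnorm(1000))))
  for (i in 1:10) {
    on <- sample(900, 1)
    m <- event_metrics(on, on + 50, tr)
    expect_gte(m$peak_velocity, m$mean_velocity)
  }
  expect_error(event_metrics(10, 10.5, tr), "fewer than 2")
})

test_that("full detection recovers a constructed saccade between two
           fixations", {
  ## two stills joined by a fast 150 px sweep; enough samples for the
  ## adaptive threshold to stabilize
  x <- c(rep(0, 2000), seq(0, 150, length.out = 30), rep(150, 2000))
  set.seed(4)
  rec <- make_recording(x + rnorm(length(x), 0, 0.3))
  ev <- detect_events(rec)
  expect_equal(sum(ev$kind == "saccade"), 1L)
  sac <- ev[ev$kind == "saccade", ]
  expect_equal(sac$amplitude, 150 * 0.0186, tolerance = 0.15)
  expect_equal(sum(ev$kind == "fixation"), 2L)
})
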