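## Synthetic arousal-coupled gaze + PPG generator.

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(duration_s = 0), "positive")
  expect_error(sim_config(blink_rate_base = -1), "non-negative")
  expect_error(sim_config(coupling = 1.5), "coupling")
  expect_error(sim_config(base_hr = 170, hr_gain = 20), "40, 180")
})

test_that("arousal: bounded, right length, seed-deterministic, and
           mean-reverting to the stated band (Monte-Carlo)", {
  cfg <- sim_config(duration_s = 600, seed = 5)
  a1 <- simulate_arousal(cfg)
  a2 <- simulate_arousal(cfg)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 600)
  expect_true(all(a1$level >= 0 & a1$level <= 1))
  expect_gt(sd(a1$level), 0)  # it does fluctuate

  ## 10 000 replicate means of the default-length process
  means <- vapply(1:10000, function(i)
    mean(simulate_arousal(sim_config(seed = i))$level), numeric(1))
  expect_gt(mean(means), 0.3)
  expect_lt(mean(means), 0.7)
})

test_that("gaze: determinism, coupling=0 independence from arousal, and
           degenerate stillness", {
  cfg <- sim_config(duration_s = 60, seed = 2)
  ar <- simulate_arousal(cfg)
  g1 <- simulate_gaze(ar, cfg)
  g2 <- simulate_gaze(ar, cfg)
  expect_identical(g1, g2)

  ## coupling = 0: two different arousal trajectories produce bitwise
  ## identical gaze (arousal cannot reach the gaze at zero coupling)
  cfg0 <- sim_config(duration_s = 60, seed = 2, coupling = 0)
  ar_b <- simulate_arousal(sim_config(duration_s = 60, seed = 99))
  expect_false(isTRUE(all.equal(ar$level, ar_b$level)))
  expect_identical(simulate_gaze(ar, cfg0)$recording,
                   simulate_gaze(ar_b, cfg0)$recording)

  ## degenerate stillness: no drift, no saccades, no blinks, no noise
  cfg_still <- sim_config(duration_s = 30, seed = 3, drift_sd = 0,
                          saccade_rate = 0, blink_rate_base = 0,
                          blink_rate_gain = 0, noise_sd_deg = 0)
  g <- simulate_gaze(simulate_arousal(cfg_still), cfg_still)
  expect_equal(length(unique(g$recording$x_px)), 1L)
  expect_equal(length(unique(g$recording$y_px)), 1L)
  expect_equal(sum(g$truth$events$kind == "saccade"), 0L)
  expect_equal(nrow(g$truth$blinks), 0L)

  expect_error(simulate_gaze(ar[0, ], cfg), "empty")
})

test_that("gaze ground truth: streams are time-ordered, non-overlapping,
           and blink counts at coupling=0 follow the Poisson expectation", {
  cfg <- sim_config(duration_s = 7200, seed = 11, coupling = 0)
  g <- simulate_gaze(simulate_arousal(cfg), cfg)
  ev <- g$truth$events
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$offset - ev$onset > 0))
  expect_true(all(ev$onset[-1] - ev$offset[-nrow(ev)] > -1e-9))
  bl <- g$truth$blinks
  expect_true(all(bl$onset[-1] > bl$offset[-nrow(bl)]))

  ## coupling = 0: rate = blink_rate_base (5/min) -> 600 expected over 2 h,
  ## within a 3 sigma Poisson band
  expected <- cfg$blink_rate_base * 120
  expect_gt(nrow(bl), expected - 3 * sqrt(expected))
  expect_lt(nrow(bl), expected + 3 * sqrt(expected))
  ## detector agrees with the truth on clean data
  expect_equal(nrow(detect_blinks(g$recording)), nrow(bl), tolerance = 0.01)
})

test_that("ppg: rate formula, exact beat spacing without noise, bounded
           true heart rate, determinism", {
  ## constant arousal 0.5, base 60 + gain 20 -> 70 bpm throughout
  ar <- constant_arousal(0.5, 30)
  cfg <- sim_config(duration_s = 30, base_hr = 60, hr_gain = 20,
                    hr_noise_sd = 0, ppg_noise_sd = 0, seed = 1)
  p <- simulate_ppg(ar, cfg)
  expect_equal(p$truth$hr_bpm, rep(70, 30))
  expect_true(all(p$truth$hr_bpm >= 40 & p$truth$hr_bpm <= 180))
  expect_identical(p, simulate_ppg(ar, cfg))

  ## noiseless 60 bpm: systolic peaks exactly 1 s apart (period = 100
  ## samples at 100 Hz, so the sampled waveform repeats exactly)
  cfg60 <- sim_config(duration_s = 30, base_hr = 60, hr_gain = 0,
                      hr_noise_sd = 0, ppg_noise_sd = 0, seed = 1)
  p60 <- simulate_ppg(constant_arousal(0.5, 30), cfg60)
  v <- p60$recording$value
  pk <- which(diff(sign(diff(v))) == -2) + 1
  pk <- pk[v[pk] > 0.5]  # systolic peaks only (dicrotic bump is lower)
  expect_equal(unique(diff(pk)), 100L)

  ## default config: true rate stays within physiology
  cfgd <- sim_config(duration_s = 300, seed = 8)
  pd <- simulate_ppg(simulate_arousal(cfgd), cfgd)
  expect_true(all(pd$truth$hr_bpm >= 40 & pd$truth$hr_bpm <= 180))
})

test_that("participant_config jitters baselines reproducibly and keeps the
           config valid", {
  base <- sim_config(duration_s = 60, seed = 4)
  p1 <- participant_config(base, 1)
  p1b <- participant_config(base, 1)
  p2 <- participant_config(base, 2)
  expect_identical(p1, p1b)
  expect_false(p1$blink_rate_base == p2$blink_rate_base)
  expect_s3_class(p1, "oc_sim_config")
  expect_true(p1$base_hr >= 45 && p1$base_hr <= 110)
  expect_false(p1$seed == p2$seed)
})

test_that("recordings round-trip through the text formats in both missing
           encodings", {
  cfg <- sim_config(duration_s = 20, seed = 6)
  ses <- simulate_session(cfg)
  td <- withr::local_tempdir()
  for (enc in c("nan", "zero")) {
    f <- file.path(td, paste0("gaze_", enc, ".tsv"))
    write_gaze_tsv(ses$gaze$recording, f, missing = enc)
    back <- read_gaze_tsv(f)
    expect_equal(back$x_px, ses$gaze$recording$x_px, tolerance = 1e-9)
    expect_equal(is.na(back$pupil), is.na(ses$gaze$recording$pupil))
  }
  f <- file.path(td, "ppg.csv")
  write_ppg_csv(ses$ppg$recording, f)
  expect_equal(read_ppg_csv(f)$value, ses$ppg$recording$value,
               tolerance = 1e-9)
  write_ground_truth_json(ses$gaze$truth, file.path(td, "truth.json"))
  tr <- jsonlite::read_json(file.path(td, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$events$onset, ses$gaze$truth$events$onset,
               tolerance = 1e-9)
})
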