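test_that("band-pass filter passes the band and rejects DC and drift", {
  rate <- 5000
  t <- seq(0, 2, by = 1 / rate)
  dc <- bandpass_emg(rep(1, length(t)), rate)
  # steady state (away from the zero-phase filter edge transients)
  expect_lt(max(abs(dc[t > 0.5 & t < 1.5])), 1e-6)
  mid <- bandpass_emg(sin(2 * pi * 300 * t), rate)
  expect_equal(max(abs(mid[t > 0.5 & t < 1.5])), 1, tolerance = 0.05)
  slow <- bandpass_emg(sin(2 * pi * 5 * t), rate)
  expect_lt(max(abs(slow[t > 0.5 & t < 1.5])), 10^(-20 / 20))
  expect_error(bandpass_emg(rep(0, 10), rate = 1500),
               class = "quadgait_param_error")
})

test_that("envelope is zero for silence and linear in amplitude", {
  rate <- 5000
  expect_equal(emg_envelope(rep(0, rate), rate), rep(0, rate))
  set.seed(2)
  x <- rnorm(rate)
  e1 <- emg_envelope(x, rate)
  e3 <- emg_envelope(3 * x, rate)
  expect_equal(e3, 3 * e1, tolerance = 1e-12)
})

test_that("envelope tracks the generator's modulation", {
  cfg <- quiet_config(cycles_per_animal = 20)
  cfg$noise$emg_noise <- 0.05
  an <- quiet_animal(cfg)
  sched <- build_footfall_schedule(an, 20, timing_jitter = 0)
  set.seed(11)
  emg <- synthesize_emg(sched, an, cfg,
                        channels = tibble::tibble(side = "right",
                                                  muscle = "ST"))
  env <- emg_envelope(bandpass_emg(emg$value, cfg$emg_rate), cfg$emg_rate)
  # reconstruct the true gate profile (swing-gated flexor)
  rows <- sched[sched$limb == "ipsi_hind", ]
  gate <- rep(0, length(emg$time))
  ramp <- 0.020
  for (r in seq_len(nrow(rows))) {
    a <- rows$stance_offset[r]; b <- rows$next_onset[r]
    sel <- emg$time >= a & emg$time < b
    tt <- emg$time[sel]
    g <- rep(1, length(tt))
    g[tt < a + ramp] <- 0.5 * (1 - cos(pi * (tt[tt < a + ramp] - a) / ramp))
    g[tt > b - ramp] <- 0.5 * (1 - cos(pi * (b - tt[tt > b - ramp]) / ramp))
    gate[sel] <- g
  }
  sel <- emg$time > 1 & emg$time < 19
  expect_gt(cor(env[sel], gate[sel]), 0.95)
})

test_that("burst detector: silence, retention of the longest burst, full window", {
  rate <- 1000
  t <- seq(0, 4, by = 1 / rate)
  base <- abs(rnorm(length(t), 0, 0.01))
  expect_true(all(is.na(
    detect_bursts(base, t, tibble::tibble(start = 0:2, end = 1:3))$onset)))
  env <- base
  env[t >= 1.1 & t < 1.2] <- 1    # short burst
  env[t >= 1.5 & t < 1.8] <- 1    # longer burst, same window
  d <- detect_bursts(env, t, tibble::tibble(start = 1, end = 2))
  expect_equal(d$onset, 1.5, tolerance = 0.02)
  expect_equal(d$offset, 1.8, tolerance = 0.02)
  # a window of sustained tonic activity: full-window burst, flagged
  env2 <- base
  env2[t >= 0.9 & t < 2.1] <- 1
  d2 <- detect_bursts(env2, t, tibble::tibble(start = 1, end = 2))
  expect_true(d2$full_window)
  expect_equal(d2$onset, 1)
  expect_equal(d2$offset, 2)
})

test_that("burst metrics: constant amplitude, identity normalization, errors", {
  t <- seq(0, 1, by = 1e-3)
  bm <- burst_metrics(t, rep(2.5, length(t)), 0.2, 0.7)
  expect_equal(bm$mean_amplitude, 2.5)
  expect_equal(bm$duration, 0.5)
  bm2 <- burst_metrics(t, rep(2.5, length(t)), 0.2, 0.7, control_mean = 2.5)
  expect_equal(bm2$normalized_amplitude, 100)
  expect_error(burst_metrics(t, rep(1, length(t)), 0.2, 0.7,
                             control_mean = 0),
               class = "quadgait_normalization_error")
})

test_that("mean amplitude is invariant to burst-internal time reversal", {
  set.seed(9)
  t <- seq(0, 1, by = 1e-3)
  r <- abs(rnorm(length(t)))
  sel <- t >= 0.3 & t <= 0.6
  r2 <- r
  r2[sel] <- rev(r[sel])
  expect_equal(burst_metrics(t, r, 0.3, 0.6)$mean_amplitude,
               burst_metrics(t, r2, 0.3, 0.6)$mean_amplitude)
})

test_that("normalized amplitudes are invariant to channel rescaling", {
  cfg <- quiet_config(cycles_per_animal = 25,
                      phase_targets = "stance_to_swing",
                      stimuli_per_phase = 3,
                      profiles = list(stance_to_swing = perturbation_profile(
                        emg_amplitude_gain = c(ipsi_hind.ST = 3.51))))
  cfg$noise$emg_noise <- 0.05
  set.seed(13)
  ses <- simulate_session(cfg, markers = FALSE,
                          emg_channels = tibble::tibble(side = "right",
                                                        muscle = "ST"))
  cyc <- schedule_cycles(ses$schedule)
  tri <- extract_triads(ses$stimuli, cyc)
  em1 <- emg_triad_metrics(tri, cyc, ses$emg)
  emg_scaled <- dplyr::mutate(ses$emg, value = value * 37.5)
  attributes(emg_scaled) <- attributes(ses$emg)
  emg_scaled$value <- ses$emg$value * 37.5
  em2 <- emg_triad_metrics(tri, cyc, emg_scaled)
  n1 <- dplyr::filter(em1, variable == "emg_normalized_amplitude")
  n2 <- dplyr::filter(em2, variable == "emg_normalized_amplitude")
  expect_equal(n1$value, n2$value, tolerance = 1e-9)
  # control normalizes to 100% by construction
  expect_true(all(abs(n1$value[n1$cycle_role == "control"] - 100) < 1e-9))
  # injected amplitude gain is recovered in the stimulated cycle
  stim <- n1$value[n1$cycle_role == "stim"]
  expect_equal(mean(stim), 351, tolerance = 0.1)
})
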