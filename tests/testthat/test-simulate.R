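test_that("noiseless toe kinematics follow the belt and bell construction", {
  cfg <- quiet_config(cycles_per_animal = 6)
  an <- quiet_animal(cfg)
  sched <- build_footfall_schedule(an, 6, timing_jitter = 0)
  mk <- synthesize_markers(sched, an, cfg, marker_jitter = 0)
  toe <- dplyr::filter(mk, side == "right", landmark == "hind_toe")
  # mid-stance: toe on the belt
  expect_equal(toe$y[toe$time == 2.3], 0)
  # apex of the swing bell is attained exactly
  expect_equal(max(toe$y[toe$time >= 2 & toe$time < 3]),
               an$swing_apex_hind)
  # horizontal displacement over one stance = belt speed x stance duration
  x_on <- toe$x[toe$time == 2]
  x_off <- toe$x[toe$time == 2.65]
  expect_equal(x_on - x_off, cfg$belt_speed * 0.65, tolerance = 1e-12)
})

test_that("prescribed joint angles are recovered from the markers", {
  cfg <- quiet_config(cycles_per_animal = 4)
  an <- quiet_animal(cfg)
  sched <- build_footfall_schedule(an, 4, timing_jitter = 0)
  mk <- synthesize_markers(sched, an, cfg, marker_jitter = 0)
  s <- dplyr::filter(mk, side == "right")
  g <- function(lm) dplyr::arrange(dplyr::filter(s, landmark == lm), frame)
  il <- g("iliac_crest"); tr <- g("trochanter"); kn <- g("knee")
  ml <- g("malleolus"); mt <- g("mtp")
  tt <- quadgait:::toe_traj(sched, "ipsi_hind", il$time, cfg$belt_speed,
                            0.13, an$swing_apex_hind)
  expect_equal(joint_angle(il$x, il$y, tr$x, tr$y, kn$x, kn$y),
               110 + 15 * cos(2 * pi * (tt$phase - 0.05)),
               tolerance = 1e-6)
  expect_equal(joint_angle(tr$x, tr$y, kn$x, kn$y, ml$x, ml$y),
               115 + 20 * cos(2 * pi * (tt$phase - 0.55)),
               tolerance = 1e-6)
  expect_equal(joint_angle(kn$x, kn$y, ml$x, ml$y, mt$x, mt$y),
               110 + 20 * cos(2 * pi * (tt$phase - 0.85)),
               tolerance = 1e-6)
})

test_that("identity profile leaves the stimulated cycle unperturbed", {
  cfg <- quiet_config(profiles = list(
    mid_swing = perturbation_profile()))
  set.seed(4)
  ses <- simulate_session(cfg, markers = FALSE)
  ref <- build_footfall_schedule(quiet_animal(cfg), cfg$cycles_per_animal,
                                 timing_jitter = 0)
  expect_equal(ses$schedule$stance_onset, ref$stance_onset)
  expect_equal(ses$schedule$stance_offset, ref$stance_offset)
  expect_equal(nrow(ses$truth), 0L)
})

test_that("temporal multipliers are realized exactly off the frame grid", {
  for (m in c(0.5, 1.235, 2)) {
    # large swing prolongations need the cycle extended as well so that
    # the following (resynchronizing) cycle keeps a positive duration
    cyc_m <- if (m > 1.3) 0.65 + 0.35 * m else 1
    cfg <- quiet_config(
      cycles_per_animal = 30,
      phase_targets = "mid_swing", stimuli_per_phase = 2,
      profiles = list(mid_swing = perturbation_profile(
        swing_multiplier = c(ipsi_hind = m),
        cycle_multiplier = c(ipsi_hind = cyc_m))))
    an <- quiet_animal(cfg)
    sched <- build_footfall_schedule(an, cfg$cycles_per_animal,
                                     timing_jitter = 0, frame_rate = NULL)
    set.seed(1)
    inj <- inject_stimuli(sched, cfg)
    cyc <- schedule_cycles(inj$schedule)
    tri <- extract_triads(inj$stimuli, cyc)
    met <- triad_duration_metrics(tri, cyc, support = FALSE)
    w <- tidyr::pivot_wider(
      dplyr::filter(met, variable == "swing_duration", limb == "ipsi_hind"),
      names_from = "cycle_role", values_from = "value")
    expect_equal(w$stim / w$control, rep(m, nrow(w)), tolerance = 1e-9)
  }
})

test_that("injected toe height and step length gains are exact at zero noise", {
  cfg <- quiet_config(
    cycles_per_animal = 20, phase_targets = "mid_swing",
    profiles = list(mid_swing = perturbation_profile(
      toe_height_gain = 4.584,
      step_length_multiplier = c(contra_hind = 0.867))))
  set.seed(2)
  ses <- simulate_session(cfg)
  cyc <- detect_cycles(ses$markers)
  tri <- extract_triads(ses$stimuli, cyc)
  met <- triad_metrics(tri, cyc, ses$markers, height_smooth_hz = NULL)
  w <- tidyr::pivot_wider(met, names_from = "cycle_role",
                          values_from = "value")
  toe <- dplyr::filter(w, variable == "toe_height", limb == "ipsi_hind")
  expect_equal(toe$stim / toe$control, 4.584, tolerance = 1e-9)
  stp <- dplyr::filter(w, variable == "step_length", limb == "contra_hind")
  expect_equal(stp$stim / stp$control, 0.867, tolerance = 1e-9)
})

test_that("stimuli that cannot fit the spacing raise a scheduling error", {
  cfg <- quiet_config(cycles_per_animal = 12, stimuli_per_phase = 10)
  an <- quiet_animal(cfg)
  sched <- build_footfall_schedule(an, 12, timing_jitter = 0)
  set.seed(1)
  expect_error(inject_stimuli(sched, cfg),
               class = "quadgait_scheduling_error")
})

test_that("EMG synthesis: gains scale burst amplitude, gate count matches cycles", {
  cfg <- quiet_config(cycles_per_animal = 50)
  cfg$noise$emg_noise <- 0.05
  an <- quiet_animal(cfg)
  sched <- build_footfall_schedule(an, 50, timing_jitter = 0)
  chan <- tibble::tibble(side = "right", muscle = "ST")
  set.seed(6)
  emg1 <- synthesize_emg(sched, an, cfg, channels = chan)
  an2 <- an
  an2$emg_amp[["ST"]] <- 2
  set.seed(6)
  emg2 <- synthesize_emg(sched, an2, cfg, channels = chan)
  env1 <- emg_envelope(bandpass_emg(emg1$value, cfg$emg_rate), cfg$emg_rate)
  env2 <- emg_envelope(bandpass_emg(emg2$value, cfg$emg_rate), cfg$emg_rate)
  win <- tibble::tibble(start = 2:48, end = 3:49)
  d1 <- detect_bursts(env1, emg1$time, win)
  d2 <- detect_bursts(env2, emg2$time, win)
  # one burst per cycle
  expect_gte(mean(!is.na(d1$onset)), 0.98)
  amp <- function(emg, d) {
    rect <- abs(bandpass_emg(emg$value, cfg$emg_rate))
    mean(vapply(which(!is.na(d$onset)), function(i)
      mean(rect[emg$time >= d$onset[i] & emg$time <= d$offset[i]]),
      numeric(1)))
  }
  # doubling the envelope gain doubles the measured mean burst amplitude
  expect_equal(amp(emg2, d2) / amp(emg1, d1), 2, tolerance = 0.05)
  expect_error(synthesize_emg(sched, an, cfg,
                              channels = tibble::tibble(side = "left",
                                                        muscle = "XX")),
               class = "quadgait_param_error")
})

test_that("zero envelope gain leaves a channel at baseline noise", {
  cfg <- quiet_config(cycles_per_animal = 10)
  cfg$noise$emg_noise <- 0.05
  an <- quiet_animal(cfg)
  an$emg_amp[["SOL"]] <- 0
  sched <- build_footfall_schedule(an, 10, timing_jitter = 0)
  set.seed(8)
  emg <- synthesize_emg(sched, an, cfg,
                        channels = tibble::tibble(side = "right",
                                                  muscle = "SOL"))
  env <- emg_envelope(bandpass_emg(emg$value, cfg$emg_rate), cfg$emg_rate)
  d <- detect_bursts(env, emg$time, tibble::tibble(start = 1:8, end = 2:9))
  expect_true(all(is.na(d$onset)))
})
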