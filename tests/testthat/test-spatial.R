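test_that("step length is the horizontal separation at leading contact", {
  t <- seq(0, 1, by = 1 / 60)
  expect_equal(step_length(t, rep(0.05, 61), rep(-0.07, 61), 0.5), 0.12)
  expect_equal(step_length(t, rep(0.02, 61), rep(0.02, 61), 0.5), 0)
  expect_error(step_length(t, rep(0, 61), rep(0, 61), 2),
               class = "quadgait_input_error")
})

test_that("stride length adds the belt travel during swing", {
  t <- seq(0, 1, by = 1 / 60)
  x <- seq(0.10, -0.10, length.out = 61)
  cyc <- tibble::tibble(stance_onset = 0, stance_offset = 1,
                        next_onset = 1, swing_duration = 0.35)
  expect_equal(stride_length(cyc, t, x, 0.4), 0.20 + 0.14)
  cyc0 <- dplyr::mutate(cyc, swing_duration = 0)
  expect_equal(stride_length(cyc0, t, x, 0.4), 0.20)
})

test_that("treadmill conservation holds on noiseless steady cycles", {
  cfg <- quiet_config(cycles_per_animal = 8)
  an <- quiet_animal(cfg)
  mk <- synthesize_markers(build_footfall_schedule(an, 8, timing_jitter = 0),
                           an, cfg, marker_jitter = 0)
  cyc <- detect_cycles(mk)
  toe <- dplyr::arrange(
    dplyr::filter(mk, side == "right", landmark == "hind_toe"), frame)
  ip <- dplyr::filter(cyc, limb == "ipsi_hind", cycle %in% 2:6)
  for (i in seq_len(nrow(ip))) {
    sl <- stride_length(ip[i, ], toe$time, toe$x, cfg$belt_speed)
    expect_lt(abs(sl - cfg$belt_speed * ip$cycle_duration[i]), 1e-6)
  }
})

test_that("joint angles: canonical geometries and rigid-motion invariance", {
  expect_equal(joint_angle(0, 1, 0, 0, 0, -1), 180)
  expect_equal(joint_angle(0, 1, 0, 0, 1, 0), 90)
  expect_true(is.na(joint_angle(0, 0, 0, 0, 1, 1)))
  set.seed(5)
  p <- matrix(rnorm(6), 3)
  base <- joint_angle(p[1, 1], p[1, 2], p[2, 1], p[2, 2], p[3, 1], p[3, 2])
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  q <- sweep(p %*% t(R), 2, c(1.3, -0.7), "+")
  rot <- joint_angle(q[1, 1], q[1, 2], q[2, 1], q[2, 2], q[3, 1], q[3, 2])
  expect_equal(rot, base, tolerance = 1e-9)
})

test_that("angle summaries handle constants and missing data", {
  t <- seq(0, 1, by = 1 / 60)
  cyc <- tibble::tibble(stance_onset = 0, stance_offset = 0.65,
                        next_onset = 0.999)
  s <- angle_summary(t, rep(95, 61), cyc)
  expect_equal(s$excursion, 0)
  expect_equal(s$max, s$at_contact)
  expect_true(s$valid)
  a <- rep(95, 61); a[1:10] <- NA  # ~16% missing
  expect_false(angle_summary(t, a, cyc)$valid)
})

test_that("support decomposition through the pipeline matches the oracle", {
  set.seed(77)
  cfg <- quiet_config(cycles_per_animal = 10)
  an <- quiet_animal(cfg)
  sched <- build_footfall_schedule(an, 10, timing_jitter = 0.01)
  cyc <- schedule_cycles(sched)
  iv <- dplyr::select(cyc, limb, onset = stance_onset,
                      offset = stance_offset)
  w <- dplyr::filter(cyc, limb == "ipsi_hind", cycle == 4)
  per <- support_periods(iv, w$stance_onset, w$next_onset)
  bf <- brute_support(iv, w$stance_onset, w$next_onset, resolution = 3000)
  expect_equal(per$limbs, bf$limbs)
})

test_that("maximum heights are exact at zero noise, including injected gains", {
  cfg <- quiet_config(
    cycles_per_animal = 20, phase_targets = "stance_to_swing",
    profiles = list(stance_to_swing = perturbation_profile(
      toe_height_gain = 4.584)))
  set.seed(3)
  ses <- simulate_session(cfg)
  cyc <- detect_cycles(ses$markers)
  tri <- extract_triads(ses$stimuli, cyc)
  met <- triad_metrics(tri, cyc, ses$markers, height_smooth_hz = NULL)
  w <- tidyr::pivot_wider(
    dplyr::filter(met, variable == "toe_height", limb == "ipsi_hind"),
    names_from = "cycle_role", values_from = "value")
  expect_equal(w$control, 0.03, tolerance = 1e-12)
  expect_equal(w$stim / w$control, 4.584, tolerance = 1e-9)
})

test_that("left and right hind step lengths agree for symmetric gait", {
  cfg <- quiet_config(cycles_per_animal = 8)
  an <- quiet_animal(cfg)
  mk <- synthesize_markers(build_footfall_schedule(an, 8, timing_jitter = 0),
                           an, cfg, marker_jitter = 0)
  cyc <- detect_cycles(mk)
  g <- function(s) dplyr::arrange(
    dplyr::filter(mk, side == s, landmark == "hind_toe"), frame)
  r <- g("right"); l <- g("left")
  on_r <- dplyr::filter(cyc, limb == "ipsi_hind", cycle == 4)$stance_onset
  on_l <- dplyr::filter(cyc, limb == "contra_hind", cycle == 4)$stance_onset
  sr <- step_length(r$time, r$x, l$x, on_r)
  sl <- step_length(l$time, l$x, r$x, on_l)
  expect_lt(abs(sr - sl), 1e-9)
})
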