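test_that("contact detection requires an observed swing-to-stance transition", {
  t <- seq(0, 2, by = 1 / 60)
  expect_equal(detect_stance_onsets(t, rep(0, length(t))), numeric(0))
  expect_error(detect_stance_onsets(0.5, 0), class = "quadgait_input_error")
  expect_error(detect_stance_onsets(t, c(NA, rep(0, length(t) - 1))),
               class = "quadgait_input_error")
})

test_that("noiseless detection matches the schedule within one frame", {
  cfg <- quiet_config(cycles_per_animal = 8)
  an <- quiet_animal(cfg)
  sched <- build_footfall_schedule(an, 8, timing_jitter = 0)
  mk <- synthesize_markers(sched, an, cfg, marker_jitter = 0)
  cyc <- detect_cycles(mk)
  truth <- schedule_cycles(sched)
  cmp <- dplyr::inner_join(
    cyc, truth, by = c("limb", "stance_onset"), suffix = c("", "_t"))
  expect_gt(nrow(cmp), 20)
  expect_true(all(abs(cmp$stance_offset - cmp$stance_offset_t) <= 1 / 60))
  expect_true(all(abs(cmp$cycle_duration - cmp$cycle_duration_t) <= 1 / 60))
  # mean cycle duration equals the configured period within one frame
  expect_lt(abs(mean(cyc$cycle_duration) - an$cycle_period), 1 / 60)
})

test_that("marker jitter of 1 mm rarely moves events by more than a frame", {
  cfg <- quiet_config(cycles_per_animal = 40)
  an <- quiet_animal(cfg)
  sched <- build_footfall_schedule(an, 40, timing_jitter = 0)
  set.seed(15)
  mk <- synthesize_markers(sched, an, cfg, marker_jitter = 0.001)
  cyc <- detect_cycles(mk)
  truth <- schedule_cycles(sched)
  cmp <- dplyr::inner_join(
    dplyr::mutate(cyc, key = round(stance_onset * 60)),
    dplyr::mutate(truth, key = round(stance_onset * 60)),
    by = c("limb", "key"), suffix = c("", "_t"))
  expect_gt(nrow(cmp), 120)
  ok <- abs(cmp$stance_offset - cmp$stance_offset_t) <= 1 / 60 + 1e-9
  expect_gte(mean(ok), 0.95)
})

test_that("offsets are undefined for motion without a swing phase", {
  t <- seq(0, 3, by = 1 / 60)
  x <- 1 - 0.4 * t  # monotone caudal drift, no swing
  offs <- detect_stance_offsets(t, x, onsets = c(0, 1, 2))
  expect_true(all(is.na(offs)))
  # a single complete cycle has exactly one offset strictly inside
  cfg <- quiet_config(cycles_per_animal = 4)
  an <- quiet_animal(cfg)
  mk <- synthesize_markers(build_footfall_schedule(an, 4, timing_jitter = 0),
                           an, cfg, marker_jitter = 0)
  toe <- dplyr::arrange(
    dplyr::filter(mk, side == "right", landmark == "hind_toe"), frame)
  off <- detect_stance_offsets(toe$time, toe$x, onsets = c(1, 2))
  expect_length(off, 1)
  expect_true(off > 1 && off < 2)
})

test_that("cycle assembly enforces interleaving and the duration identity", {
  cyc <- build_cycles(onsets = c(0, 1, 2), offsets = c(0.65, 1.65),
                      limb = "ipsi_hind")
  expect_equal(cyc$cycle_duration, c(1, 1))
  expect_equal(cyc$stance_duration, c(0.65, 0.65))
  expect_equal(cyc$swing_duration, c(0.35, 0.35))
  # identity holds exactly by construction
  expect_identical(cyc$swing_duration,
                   cyc$cycle_duration - cyc$stance_duration)
  expect_error(build_cycles(c(0, 1, 2), c(1.2, 1.65)),
               class = "quadgait_pairing_error")
  dropped <- build_cycles(c(0, 1, 2, 3), c(0.65, NA, 2.65))
  expect_equal(nrow(dropped), 2L)
})

test_that("detection is invariant to translating the coordinate origin", {
  cfg <- quiet_config(cycles_per_animal = 6)
  an <- quiet_animal(cfg)
  set.seed(21)
  mk <- synthesize_markers(build_footfall_schedule(an, 6, timing_jitter = 0),
                           an, cfg, marker_jitter = 0.001)
  mk2 <- dplyr::mutate(mk, x = x + 3.21)
  attributes(mk2) <- attributes(mk)
  mk2$x <- mk$x + 3.21
  expect_identical(detect_cycles(mk), detect_cycles(mk2))
})
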