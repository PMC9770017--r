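cycles4 <- function(n = 12) schedule_cycles(
  build_footfall_schedule(quiet_animal(), n, timing_jitter = 0))

test_that("normalized phase honours its boundary identities", {
  cyc <- dplyr::filter(cycles4(), limb == "ipsi_hind", cycle == 3)
  np <- normalized_phase(cyc$stance_onset, cyc)
  expect_equal(np$phase, 0)
  expect_equal(np$stance_fraction, 0)
  mid <- normalized_phase(cyc$stance_onset + 0.5 * cyc$stance_duration, cyc)
  expect_equal(mid$stance_fraction, 0.5)
  off <- normalized_phase(cyc$stance_offset, cyc)
  expect_equal(off$phase, 0.65)  # duty factor of the cycle
  expect_equal(off$swing_fraction, 0)
  expect_error(normalized_phase(cyc$next_onset + 0.1, cyc),
               class = "quadgait_assignment_error")
})

test_that("phase classification uses disjoint windows with exclusion", {
  expect_equal(classify_phase(0.5, NA), "mid_stance")
  expect_equal(classify_phase(0.15, NA), "excluded")
  expect_equal(classify_phase(0.95, NA), "stance_to_swing")
  expect_equal(classify_phase(0.05, NA), "swing_to_stance")
  expect_equal(classify_phase(NA, 0.5), "mid_swing")
  expect_equal(classify_phase(NA, 0.05), "stance_to_swing")
  expect_equal(classify_phase(NA, 0.95), "swing_to_stance")
  expect_equal(classify_phase(NA, 0.8), "excluded")
  expect_error(phase_windows(mid = c(0.05, 0.7)),
               class = "quadgait_config_error")
  expect_error(phase_windows(mid = c(0.7, 0.3)),
               class = "quadgait_config_error")
})

test_that("simulator stimuli classify to their target phase at zero jitter", {
  cfg <- quiet_config(cycles_per_animal = 120,
                      phase_targets = PHASE_LEVELS,
                      stimuli_per_phase = 4,
                      profiles = NULL)  # identity: classification only
  set.seed(31)
  ses <- simulate_session(cfg, markers = FALSE)
  cyc <- schedule_cycles(ses$schedule)
  tri <- extract_triads(ses$stimuli, cyc)
  got <- dplyr::distinct(tri, stim_id, phase)
  merged <- dplyr::inner_join(got, ses$stimuli, by = "stim_id")
  expect_equal(merged$phase, merged$phase_target)
  expect_true(all(tri$valid))
})

test_that("triads are assembled per limb around the stimulus", {
  cyc <- cycles4()
  st <- tibble::tibble(stim_id = 1L, onset = 5.85, side = "right")
  tri <- extract_triads(st, cyc)
  expect_equal(nrow(tri), 4L)
  expect_true(all(tri$valid))
  expect_setequal(tri$limb, LIMB_ROLES)
  ipsi <- dplyr::filter(tri, limb == "ipsi_hind")
  expect_equal(ipsi$stim_cycle, 6L)  # cycle [5, 6) contains the onset
  expect_equal(ipsi$control_cycle, 5L)
  expect_equal(ipsi$post_cycle, 7L)
  # consecutive per limb by construction
  expect_true(all(tri$post_cycle - tri$control_cycle == 2L))
})

test_that("stimuli one cycle apart invalidate both triads", {
  cyc <- cycles4()
  st <- tibble::tibble(stim_id = 1:2, onset = c(5.85, 6.85),
                       side = "right")
  tri <- extract_triads(st, cyc)
  expect_true(all(!tri$valid))
  expect_true(all(tri$reason == "stimulus_collision"))
})

test_that("stimuli outside the cycle table are skipped with a warning", {
  cyc <- cycles4()
  st <- tibble::tibble(stim_id = 1L, onset = 1e6, side = "right")
  expect_warning(tri <- extract_triads(st, cyc), regexp = "skipped")
  expect_false(any(tri$valid))
})
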