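# Shared builders for the test suite. All fixtures are generated in code.

zero_noise <- list(marker_jitter = 0, timing_jitter = 0, emg_noise = 0,
                   animal_sigma = 0)

# A small zero-noise configuration; cycle period 1 s at 60 frames/s keeps
# every schedule event exactly on the video frame grid, so detected events
# equal generated events and measured quantities equal ground truth.
quiet_config <- function(..., phase_targets = "mid_swing",
                         stimuli_per_phase = 1, cycles_per_animal = 20,
                         profiles = NULL) {
  session_config(
    n_animals = 1, cycles_per_animal = cycles_per_animal,
    stimuli_per_phase = stimuli_per_phase, phase_targets = phase_targets,
    phase_jitter = 0, noise = zero_noise,
    perturbation_profiles = profiles, ...)
}

quiet_animal <- function(cfg = quiet_config()) animal_params(cfg)

# Brute-force support-period oracle: label the in-stance limb set on a
# dense time grid and merge constant runs.
brute_support <- function(stance, ws, we, resolution = 1000) {
  n <- floor((we - ws) * resolution)
  mids <- ws + (seq_len(n) - 0.5) / resolution
  sets <- vapply(mids, function(m) {
    roles <- stance$limb[stance$onset <= m & m < stance$offset]
    paste(quadgait:::LIMB_ROLES[quadgait:::LIMB_ROLES %in% roles],
          collapse = "+")
  }, character(1))
  r <- rle(sets)
  tibble::tibble(limbs = r$values,
                 duration = r$lengths / resolution,
                 category = support_category(r$values))
}

# Random (valid) walking schedule for oracle-equivalence checks.
random_schedule <- function() {
  cfg <- session_config(noise = list(
    marker_jitter = 0, timing_jitter = runif(1, 0, 0.02),
    timing_shared = runif(1, 0.5, 1), emg_noise = 0, animal_sigma = 0.05))
  an <- animal_params(cfg)
  an$duty <- runif(1, 0.55, 0.8)
  build_footfall_schedule(an, n_cycles = 6, frame_rate = NULL)
}
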