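#' Session configuration
#'
#' Bundles the acquisition and simulation parameters of one treadmill
#' session: belt speed, sampling rates, study size, stimulation schedule and
#' the per-phase perturbation profiles used by the synthetic generator.
#'
#' Defaults follow the study conditions the pipeline is built for: cats
#' walking at 0.3--0.5 m/s, video at 60 frames/s, EMG digitized at 5000 Hz,
#' seven animals, stimulus trains delivered every five to six step cycles
#' with 5--20 stimuli per locomotor phase.
#'
#' @param belt_speed Treadmill belt speed in m/s.
#' @param frame_rate Video frame rate in Hz.
#' @param emg_rate EMG sampling rate in Hz.
#' @param n_animals Number of animals in the study.
#' @param cycles_per_animal Step cycles simulated per animal.
#' @param stim_every_cycles Integer range (length-2) of cycles between
#'   consecutive stimuli.
#' @param stimuli_per_phase Stimuli delivered per phase per animal.
#' @param phase_targets Subset of the four phase labels to stimulate.
#' @param stim_side Side of the stimulated hindlimb.
#' @param seed Integer seed; a fixed seed gives byte-identical sessions.
#' @param phase_jitter Half-width (fraction of the sub-phase) of the uniform
#'   jitter applied to stimulus placement within its target window.
#' @param noise List of noise scales: `marker_jitter` (m, per-frame Gaussian
#'   jitter on every marker coordinate), `timing_jitter` (s, Gaussian jitter
#'   on every footfall event), `emg_noise` (baseline EMG floor as a fraction
#'   of the mean burst amplitude) and `animal_sigma` (SD of the log-normal
#'   inter-animal random effects on baseline durations and EMG gains).
#' @param perturbation_profiles Named list mapping phase labels to
#'   [perturbation_profile()] objects. Defaults to identity profiles.
#' @param train Stimulus train descriptor (stored verbatim, never derived).
#' @return An object of class `session_config` (a named list).
#' @export
#' @examples
#' cfg <- session_config(n_animals = 2, cycles_per_animal = 40)
#' cfg$belt_speed
session_config <- function(belt_speed = 0.4,
                           frame_rate = 60,
                           emg_rate = 5000,
                           n_animals = 7,
                           cycles_per_animal = 220,
                           stim_every_cycles = c(5L, 6L),
                           stimuli_per_phase = 10,
                           phase_targets = PHASE_LEVELS,
                           stim_side = "right",
                           seed = 1L,
                           phase_jitter = 0.04,
                           noise = list(),
                           perturbation_profiles = NULL,
                           train = stimulus_train()) {
  noise_def <- list(marker_jitter = 0.001, timing_jitter = 0.008,
                    timing_shared = 0.85, emg_noise = 0.05,
                    animal_sigma = 0.05)
  noise <- modifyList(noise_def, as.list(noise))
  if (!is.numeric(belt_speed) || length(belt_speed) != 1 || belt_speed <= 0)
    abort("`belt_speed` must be a single positive number (m/s).",
          class = "quadgait_config_error")
  for (nm in c("frame_rate", "emg_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      abort(sprintf("`%s` must be a single positive rate (Hz).", nm),
            class = "quadgait_config_error")
  }
  if (stimuli_per_phase < 1)
    abort("`stimuli_per_phase` must be >= 1.", class = "quadgait_config_error")
  if (length(stim_every_cycles) != 2 || any(stim_every_cycles < 1))
    abort("`stim_every_cycles` must be a length-2 positive integer range.",
          class = "quadgait_config_error")
  phase_targets <- match.arg(phase_targets, PHASE_LEVELS, several.ok = TRUE)
  stim_side <- arg_match0(stim_side, c("left", "right"))
  if (any(unlist(noise) < 0))
    abort("noise scales must be >= 0.", class = "quadgait_config_error")
  if (is.null(perturbation_profiles)) {
    perturbation_profiles <- setNames(
      lapply(phase_targets, function(p) perturbation_profile()), phase_targets)
  }
  perturbation_profiles <- lapply(perturbation_profiles, as_perturbation_profile)
  structure(
    list(belt_speed = belt_speed, frame_rate = frame_rate,
         emg_rate = emg_rate, n_animals = as.integer(n_animals),
         cycles_per_animal = as.integer(cycles_per_animal),
         stim_every_cycles = as.integer(stim_every_cycles),
         stimuli_per_phase = as.integer(stimuli_per_phase),
         phase_targets = phase_targets, stim_side = stim_side,
         seed = as.integer(seed), phase_jitter = phase_jitter,
         noise = noise, perturbation_profiles = perturbation_profiles,
         train = train),
    class = "session_config")
}

#' Stimulus train descriptor
#'
#' The train parameters are stored verbatim as delivered by the stimulator;
#' the nominal train duration is a recorded value, never derived from the
#' pulse count and frequency.
#'
#' @param n_pulses Pulses per train.
#' @param pulse_width_ms Pulse width in ms.
#' @param frequency_hz Intra-train frequency in Hz.
#' @param nominal_train_duration_ms Nominal train duration in ms.
#' @param intensity_mt Intensity as a multiple of the motor threshold.
#' @return A named list of class `stimulus_train`.
#' @export
stimulus_train <- function(n_pulses = 25, pulse_width_ms = 0.2,
                           frequency_hz = 300,
                           nominal_train_duration_ms = 88,
                           intensity_mt = 1.2) {
  vals <- c(n_pulses, pulse_width_ms, frequency_hz,
            nominal_train_duration_ms, intensity_mt)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("train parameters must be positive.",
          class = "quadgait_config_error")
  structure(list(n_pulses = n_pulses, pulse_width_ms = pulse_width_ms,
                 frequency_hz = frequency_hz,
                 nominal_train_duration_ms = nominal_train_duration_ms,
                 intensity_mt = intensity_mt),
            class = "stimulus_train")
}

#' Perturbation profile for one stimulation phase
#'
#' Describes how the stimulated cycle deviates from an unperturbed cycle.
#' Temporal effects are multiplicative on per-limb swing and cycle
#' durations; support-period effects are multiplicative on the duration of a
#' named support category relative to the control cycle; spatial and EMG
#' effects are multiplicative gains. The identity profile (all multipliers
#' 1, all deltas 0) leaves the cycle unchanged.
#'
#' @param swing_multiplier Named numeric vector, limb role -> multiplier on
#'   that limb's swing duration in its stimulated cycle.
#' @param cycle_multiplier Named numeric vector, limb role -> multiplier on
#'   cycle duration (stance absorbs the difference).
#' @param support_multiplier Named numeric vector, support category ->
#'   multiplier on that category's duration in the stimulated window,
#'   relative to the control window.
#' @param toe_height_gain Multiplier on the ipsilateral swing apex height.
#' @param step_length_multiplier Named numeric vector, limb role ->
#'   multiplier on that limb's step length at its touchdown in the
#'   stimulated cycle.
#' @param joint_flexion_delta Named numeric vector, joint (`hip`, `knee`,
#'   `ankle`) -> extra flexion (degrees, positive = more flexed) applied
#'   during the ipsilateral stimulated swing.
#' @param emg_amplitude_gain Named numeric vector, `"<role>.<muscle>"` ->
#'   multiplier on that muscle's burst envelope in its stimulated cycle.
#' @param emg_duration_gain Named numeric vector, `"<role>.<muscle>"` ->
#'   multiplier on burst gate duration.
#' @param carryover Logical; if `TRUE` the post cycle keeps the temporal
#'   multipliers instead of resynchronizing.
#' @return An object of class `perturbation_profile`.
#' @export
#' @examples
#' perturbation_profile(swing_multiplier = c(ipsi_hind = 1.235),
#'                      cycle_multiplier = c(ipsi_hind = 1.060))
perturbation_profile <- function(swing_multiplier = numeric(),
                                 cycle_multiplier = numeric(),
                                 support_multiplier = numeric(),
                                 toe_height_gain = 1,
                                 step_length_multiplier = numeric(),
                                 joint_flexion_delta = numeric(),
                                 emg_amplitude_gain = numeric(),
                                 emg_duration_gain = numeric(),
                                 carryover = FALSE) {
  check_mult <- function(x, what, names_in = NULL) {
    x <- unlist(x)
    if (length(x) == 0) return(setNames(numeric(), character()))
    if (any(!is.finite(x)) || any(x <= 0))
      abort(sprintf("%s multipliers must be positive.", what),
            class = "quadgait_config_error")
    if (!is.null(names_in) && !all(names(x) %in% names_in))
      abort(sprintf("unknown names in %s: %s", what,
                    paste(setdiff(names(x), names_in), collapse = ", ")),
            class = "quadgait_config_error")
    x
  }
  swing_multiplier <- check_mult(swing_multiplier, "swing", LIMB_ROLES)
  cycle_multiplier <- check_mult(cycle_multiplier, "cycle", LIMB_ROLES)
  support_multiplier <- check_mult(support_multiplier, "support",
                                   SUPPORT_CATEGORIES)
  step_length_multiplier <- check_mult(step_length_multiplier, "step length",
                                       LIMB_ROLES)
  emg_amplitude_gain <- check_mult(emg_amplitude_gain, "EMG amplitude")
  emg_duration_gain <- check_mult(emg_duration_gain, "EMG duration")
  if (!is.finite(toe_height_gain) || toe_height_gain <= 0)
    abort("`toe_height_gain` must be positive.",
          class = "quadgait_config_error")
  joint_flexion_delta <- unlist(joint_flexion_delta)
  if (length(joint_flexion_delta) &&
      !all(names(joint_flexion_delta) %in% c("hip", "knee", "ankle")))
    abort("joint_flexion_delta names must be hip/knee/ankle.",
          class = "quadgait_config_error")
  structure(list(swing_multiplier = swing_multiplier,
                 cycle_multiplier = cycle_multiplier,
                 support_multiplier = support_multiplier,
                 toe_height_gain = toe_height_gain,
                 step_length_multiplier = step_length_multiplier,
                 joint_flexion_delta = joint_flexion_delta,
                 emg_amplitude_gain = emg_amplitude_gain,
                 emg_duration_gain = emg_duration_gain,
                 carryover = isTRUE(carryover)),
            class = "perturbation_profile")
}

as_perturbation_profile <- function(x) {
  if (inherits(x, "perturbation_profile")) return(x)
  do.call(perturbation_profile, as.list(x))
}

is_identity_profile <- function(p) {
  length(p$swing_multiplier) == 0 && length(p$cycle_multiplier) == 0 &&
    length(p$support_multiplier) == 0 && p$toe_height_gain == 1 &&
    length(p$step_length_multiplier) == 0 &&
    length(p$joint_flexion_delta) == 0 &&
    length(p$emg_amplitude_gain) == 0 && length(p$emg_duration_gain) == 0
}

#' Read and write session configuration (YAML)
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns a validated [session_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("config file not found: ", path),
          class = "quadgait_io_error")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$perturbation_profiles))
    raw$perturbation_profiles <- lapply(raw$perturbation_profiles,
                                        as_perturbation_profile)
  if (!is.null(raw$train)) raw$train <- do.call(stimulus_train, raw$train)
  do.call(session_config, raw)
}

#' @rdname read_config
#' @param config A [session_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  x <- unclass(config)
  x$perturbation_profiles <- lapply(x$perturbation_profiles, function(p) {
    p <- unclass(p)
    p <- p[lengths(p) > 0 | names(p) %in% c("toe_height_gain", "carryover")]
    # YAML drops the names of length-1 named vectors; maps survive
    lapply(p, function(v) if (!is.null(names(v))) as.list(v) else v)
  })
  x$train <- unclass(x$train)
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' Reference phase-effect profiles
#'
#' Returns the shipped per-phase perturbation profiles whose effect sizes
#' are transcribed from group results reported for superficial peroneal
#' nerve stimulation during quadrupedal treadmill locomotion in intact cats
#' (e.g. +23.5% ipsilateral swing duration at mid-swing, +358.4%
#' ipsilateral maximum toe height at the stance-to-swing transition). They
#' parameterize the synthetic generator for parameter-recovery validation.
#'
#' @return Named list of [perturbation_profile()] objects, one per phase.
#' @export
#' @examples
#' profs <- reference_phase_effects()
#' profs$mid_swing$swing_multiplier
reference_phase_effects <- function() {
  path <- system.file("extdata", "phase_effects.yaml", package = "quadgait",
                      mustWork = TRUE)
  lapply(yaml::read_yaml(path), as_perturbation_profile)
}
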