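#' Per-animal baseline gait parameters
#'
#' Draws one animal's baseline locomotor parameters. Inter-animal
#' variability is multiplicative log-normal on baseline durations, segment
#' lengths and EMG gains (`noise$animal_sigma`), giving the repeated-measures
#' blocks realistic heterogeneity.
#'
#' @param config A [session_config()].
#' @param id Animal identifier (integer or string).
#' @return A named list of class `animal_params`: cycle period (s), duty
#'   factor, limb phase offsets (fractions of a cycle), segment lengths (m),
#'   girdle heights (m), swing apex heights (m), per-muscle EMG baseline
#'   amplitudes (arbitrary units) and noise scales.
#' @export
animal_params <- function(config, id = 1L) {
  sig <- config$noise$animal_sigma
  ln <- function(base, s = sig) base * exp(rnorm(1L, 0, s))
  # duty factor is held at the canonical walking value for every animal:
  # the planted support-period effects are expressed relative to the
  # canonical phasing, whose double-support gaps scale with (offset - duty),
  # so per-animal duty variation would make large planted support targets
  # unrepresentable within the swing envelope
  duty <- 0.65
  # one body-size factor scales segments and girdle heights together, so
  # ground clearance of the kinematic chain is size-invariant
  size <- exp(rnorm(1L, 0, sig / 2))
  structure(list(
    animal_id = id,
    cycle_period = ln(1.0),
    duty = duty,
    phase_offsets = c(ipsi_hind = 0, contra_hind = 0.5,
                      homo_fore = 0.25, diag_fore = 0.75),
    segments = list(
      thigh = 0.105 * size, shank = 0.115 * size, foot = 0.065 * size,
      arm = 0.10 * size, forearm = 0.10 * size, paw = 0.05 * size),
    hip_height = 0.26 * size,
    shoulder_height = 0.28 * size,
    girdle_sway = 0.004,
    swing_apex_hind = 0.03,
    swing_apex_fore = 0.02,
    emg_amp = setNames(vapply(ALL_MUSCLES, function(m) ln(1.0),
                              numeric(1)), ALL_MUSCLES),
    noise = config$noise
  ), class = "animal_params")
}

#' Build a periodic footfall schedule
#'
#' Generates per-limb stance intervals for a walking gait: each limb steps
#' with the animal's cycle period and duty factor, phase-shifted by the
#' limb's offset (defaults 0 / 0.5 / 0.25 / 0.75 for the ipsilateral
#' hindlimb, contralateral hindlimb, homolateral and diagonal forelimbs).
#' This lateral-sequence phasing yields the canonical eight support periods
#' per cycle. Gaussian timing jitter is added independently to every event.
#'
#' The schedule includes one margin cycle before time zero and after the
#' nominal record so that trajectories and triads near the record edges are
#' well defined.
#'
#' @param animal An [animal_params()] object.
#' @param n_cycles Number of interior step cycles.
#' @param timing_jitter SD (s) of the per-event timing jitter; defaults to
#'   the animal's noise scale.
#' @return A tibble of class `footfall_schedule` with columns `limb`
#'   (role), `cycle` (integer), `stance_onset`, `stance_offset`,
#'   `next_onset` (s), and attributes `cycle_period`, `duty`,
#'   `phase_offsets` and `duration`.
#' @export
#' @examples
#' an <- animal_params(session_config(noise = list(animal_sigma = 0)))
#' sched <- build_footfall_schedule(an, n_cycles = 10, timing_jitter = 0)
#' head(sched)
build_footfall_schedule <- function(animal, n_cycles,
                                    timing_jitter = animal$noise$timing_jitter,
                                    timing_shared = animal$noise$timing_shared %||% 0.85,
                                    frame_rate = 60) {
  T <- animal$cycle_period
  duty <- animal$duty
  if (!is.finite(duty) || duty <= 0 || duty >= 1)
    abort("duty factor must lie strictly in (0, 1).",
          class = "quadgait_param_error")
  offs <- animal$phase_offsets
  if (any(offs < 0 | offs >= 1))
    abort("phase offsets must lie in [0, 1).",
          class = "quadgait_param_error")
  ks <- 0:(n_cycles + 2L)
  # timing jitter decomposes into a rhythm component shared by all events
  # of one cycle (speed/cadence fluctuation, variance share
  # `timing_shared`) plus independent per-event noise; inter-limb
  # intervals within a cycle are much tighter than the cycle-to-cycle
  # variability, as in steady walking
  s_c <- timing_jitter * sqrt(timing_shared)
  s_e <- timing_jitter * sqrt(1 - timing_shared)
  common <- if (timing_jitter > 0) rnorm(length(ks), 0, s_c) else
    numeric(length(ks))
  snap <- function(t) if (is.null(frame_rate)) t else
    round(t * frame_rate) / frame_rate
  rows <- lapply(LIMB_ROLES, function(lb) {
    onsets <- (ks - 1 + offs[[lb]]) * T + common
    if (timing_jitter > 0)
      onsets <- onsets + rnorm(length(onsets), 0, s_e)
    onsets <- sort(onsets)
    noff <- length(onsets) - 1L
    offsets <- onsets[seq_len(noff)] + duty * T
    if (timing_jitter > 0)
      offsets <- offsets + rnorm(noff, 0, s_e)
    # keep onset < offset < next onset despite jitter
    lo <- onsets[seq_len(noff)] + 0.05 * T
    hi <- onsets[-1L] - 0.05 * T
    offsets <- pmin(pmax(offsets, lo), hi)
    # kinematic event times live on the video frame grid
    tibble(limb = lb, cycle = ks[seq_len(noff)],
           stance_onset = snap(onsets[seq_len(noff)]),
           stance_offset = snap(offsets),
           next_onset = snap(onsets[-1L]))
  })
  out <- bind_rows(rows)
  structure(out,
            class = c("footfall_schedule", class(out)),
            cycle_period = T, duty = duty, phase_offsets = offs,
            n_cycles = as.integer(n_cycles),
            duration = n_cycles * T, frame_rate = frame_rate)
}

# Preserve attributes through dplyr verbs used internally.
reclass_schedule <- function(new, old) {
  structure(new, class = c("footfall_schedule", class(tibble())),
            cycle_period = attr(old, "cycle_period"),
            duty = attr(old, "duty"),
            phase_offsets = attr(old, "phase_offsets"),
            n_cycles = attr(old, "n_cycles"),
            duration = attr(old, "duration"),
            frame_rate = attr(old, "frame_rate"))
}

#' Stance intervals of a schedule
#'
#' @param schedule A `footfall_schedule`.
#' @param limbs Limb roles to include.
#' @return Tibble with columns `limb`, `onset`, `offset`.
#' @export
schedule_stance_intervals <- function(schedule, limbs = LIMB_ROLES) {
  schedule |>
    filter(.data$limb %in% limbs) |>
    select(limb = "limb", onset = "stance_onset", offset = "stance_offset") |>
    as_tibble()
}

# Index (row within limb) of the cycle whose [onset, next_onset) contains t.
schedule_cycle_at <- function(schedule, limb_role, t) {
  sub <- schedule[schedule$limb == limb_role, , drop = FALSE]
  i <- which(sub$stance_onset <= t & t < sub$next_onset)
  if (length(i) != 1) return(NA_integer_)
  sub$cycle[i]
}

# Replace one limb-cycle row's events, propagating next_onset to the
# neighbouring rows of that limb so the schedule stays consistent.
schedule_set_events <- function(schedule, limb_role, cycle,
                                stance_onset = NULL, stance_offset = NULL,
                                next_onset = NULL) {
  i <- which(schedule$limb == limb_role & schedule$cycle == cycle)
  stopifnot(length(i) == 1)
  fr <- attr(schedule, "frame_rate")
  snap <- function(t) if (is.null(fr)) t else round(t * fr) / fr
  if (!is.null(stance_onset)) stance_onset <- snap(stance_onset)
  if (!is.null(stance_offset)) stance_offset <- snap(stance_offset)
  if (!is.null(next_onset)) next_onset <- snap(next_onset)
  if (!is.null(stance_onset)) {
    schedule$stance_onset[i] <- stance_onset
    j <- which(schedule$limb == limb_role & schedule$cycle == cycle - 1L)
    if (length(j) == 1) schedule$next_onset[j] <- stance_onset
  }
  if (!is.null(stance_offset)) schedule$stance_offset[i] <- stance_offset
  if (!is.null(next_onset)) {
    schedule$next_onset[i] <- next_onset
    j <- which(schedule$limb == limb_role & schedule$cycle == cycle + 1L)
    if (length(j) == 1) schedule$stance_onset[j] <- next_onset
  }
  sub <- schedule[schedule$limb == limb_role, ]
  bad <- with(sub, stance_onset >= stance_offset | stance_offset >= next_onset)
  if (any(bad))
    abort("perturbation produced an inconsistent event ordering.",
          class = "quadgait_param_error")
  schedule
}
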