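#' @title Synthetic session generation
#' @description Forward model for one treadmill session: a footfall schedule
#'   drives closed-form toe trajectories (stance follows the belt, swing is
#'   a minimum-jerk advance with a flat-topped height profile), a sagittal
#'   kinematic chain driven by prescribed joint-angle waveforms places the
#'   proximal markers, and phase-gated amplitude-modulated noise generates
#'   EMG. Stimuli are injected by regenerating the affected cycles from
#'   modified schedule parameters, so the ground truth of every injected
#'   effect is exact.
#' @name simulate
NULL

min_jerk <- function(s) s^3 * (10 - 15 * s + 6 * s^2)

swing_height_profile <- function(s) {
  # steep take-off/landing with a flat apex over s in [0.4, 0.6]; the
  # sampled maximum equals the apex exactly and contact detection is not
  # biased by a slow approach to the belt
  pmax(pmin(pmin(s, 1 - s) / 0.4, 1), 0)^0.25
}

# Closed-form toe trajectory of one limb. Stance: x moves backward at belt
# speed from the cycle's anterior extreme position (AEP), y = 0. Swing:
# minimum-jerk x advance to the next AEP, bell-shaped y with per-cycle apex.
toe_traj <- function(schedule, limb, times, belt_speed, aep_base, apex_base,
                     aep_values = NULL, apex_gains = NULL) {
  rows <- schedule[schedule$limb == limb, , drop = FALSE]
  rows <- rows[order(rows$cycle), , drop = FALSE]
  n <- nrow(rows)
  onsets <- c(rows$stance_onset, rows$next_onset[n])
  offsets <- rows$stance_offset
  aep <- rep(aep_base, n + 1L)
  if (!is.null(aep_values) && nrow(aep_values)) {
    for (r in seq_len(nrow(aep_values))) {
      i <- match(aep_values$cycle[r], rows$cycle)
      if (!is.na(i)) aep[i] <- aep_values$value[r]
    }
  }
  apex <- rep(apex_base, n)
  if (!is.null(apex_gains) && nrow(apex_gains)) {
    for (r in seq_len(nrow(apex_gains))) {
      i <- match(apex_gains$cycle[r], rows$cycle)
      if (!is.na(i)) apex[i] <- apex_base * apex_gains$gain[r]
    }
  }
  ci <- findInterval(times, onsets)
  if (any(ci < 1L | ci > n))
    abort("requested times fall outside the schedule span.",
          class = "quadgait_generation_error")
  on_i <- onsets[ci]; off_i <- offsets[ci]; next_i <- onsets[ci + 1L]
  stance <- times < off_i
  pep <- aep[ci] - belt_speed * (off_i - on_i)
  s <- (times - off_i) / (next_i - off_i)
  x <- ifelse(stance, aep[ci] - belt_speed * (times - on_i),
              pep + (aep[ci + 1L] - pep) * min_jerk(s))
  y <- ifelse(stance, 0, apex[ci] * swing_height_profile(s))
  list(x = x, y = y, cycle = rows$cycle[ci],
       phase = (times - on_i) / (next_i - on_i),
       swing_s = ifelse(stance, NA_real_, s), stance = stance)
}

rot_apply <- function(ux, uy, theta_deg) {
  th <- theta_deg * pi / 180
  list(x = cos(th) * ux - sin(th) * uy, y = sin(th) * ux + cos(th) * uy)
}

unit2 <- function(x, y) {
  n <- sqrt(x^2 + y^2)
  list(x = x / n, y = y / n)
}

# Hindlimb chain: iliac crest and trochanter on a swaying pelvis; knee,
# malleolus and MTP placed so that the measured included angles at the hip
# (iliac-trochanter-knee), knee (trochanter-knee-malleolus) and ankle
# (knee-malleolus-MTP) equal the prescribed waveforms exactly.
hind_chain <- function(phase, animal, flex = NULL) {
  hip <- 110 + 15 * cos(2 * pi * (phase - 0.05))
  knee <- 115 + 20 * cos(2 * pi * (phase - 0.55))
  ankle <- 110 + 20 * cos(2 * pi * (phase - 0.85))
  if (!is.null(flex)) {
    hip <- hip - flex$hip
    knee <- knee - flex$knee
    ankle <- ankle - flex$ankle
  }
  seg <- animal$segments
  tx <- rep(0, length(phase))
  ty <- animal$hip_height + animal$girdle_sway * cos(4 * pi * phase)
  ix <- tx + 0.035; iy <- ty + 0.045
  u <- unit2(ix - tx, iy - ty)
  d1 <- rot_apply(u$x, u$y, -hip)
  kx <- tx + seg$thigh * d1$x; ky <- ty + seg$thigh * d1$y
  u2 <- list(x = -d1$x, y = -d1$y)
  d2 <- rot_apply(u2$x, u2$y, knee)
  mx <- kx + seg$shank * d2$x; my <- ky + seg$shank * d2$y
  u3 <- list(x = -d2$x, y = -d2$y)
  d3 <- rot_apply(u3$x, u3$y, -ankle)
  px <- mx + seg$foot * d3$x; py <- my + seg$foot * d3$y
  list(iliac_crest = list(x = ix, y = iy),
       trochanter = list(x = tx, y = ty),
       knee = list(x = kx, y = ky),
       malleolus = list(x = mx, y = my),
       mtp = list(x = px, y = py),
       angles = list(hip = hip, knee = knee, ankle = ankle))
}

fore_chain <- function(phase, animal) {
  shoulder <- 140 + 10 * cos(2 * pi * (phase - 0.10))
  elbow <- 130 + 15 * cos(2 * pi * (phase - 0.60))
  wrist <- 150 + 10 * cos(2 * pi * (phase - 0.30))
  seg <- animal$segments
  hx <- rep(0.28, length(phase))
  hy <- animal$shoulder_height +
    animal$girdle_sway * cos(4 * pi * phase + pi)
  sx <- hx + 0.02; sy <- hy + 0.055
  u <- unit2(sx - hx, sy - hy)
  d1 <- rot_apply(u$x, u$y, -shoulder)
  ex <- hx + seg$arm * d1$x; ey <- hy + seg$arm * d1$y
  u2 <- list(x = -d1$x, y = -d1$y)
  d2 <- rot_apply(u2$x, u2$y, elbow)
  wx <- ex + seg$forearm * d2$x; wy <- ey + seg$forearm * d2$y
  u3 <- list(x = -d2$x, y = -d2$y)
  d3 <- rot_apply(u3$x, u3$y, -wrist)
  mx <- wx + seg$paw * d3$x; my <- wy + seg$paw * d3$y
  list(scapula = list(x = sx, y = sy),
       humerus = list(x = hx, y = hy),
       elbow = list(x = ex, y = ey),
       wrist = list(x = wx, y = wy),
       mcp = list(x = mx, y = my))
}

#' Synthesize marker trajectories from a footfall schedule
#'
#' @param schedule A `footfall_schedule` (possibly perturbed).
#' @param animal An [animal_params()] object.
#' @param config A [session_config()].
#' @param cycle_mods Optional tibble of per-cycle kinematic modifications
#'   produced by [inject_stimuli()] (`limb`, `cycle`, `toe_apex_gain`,
#'   `step_mult`, `flex_hip`, `flex_knee`, `flex_ankle`).
#' @param marker_jitter SD (m) of per-frame Gaussian jitter added to every
#'   coordinate; defaults to the animal's noise scale.
#' @return A tibble of class `marker_trajectories` with columns `time`,
#'   `frame`, `side`, `landmark`, `x`, `y`; coordinates in meters, x along
#'   the direction of travel, y above the belt surface.
#' @export
synthesize_markers <- function(schedule, animal, config, cycle_mods = NULL,
                               marker_jitter = animal$noise$marker_jitter) {
  fr <- config$frame_rate
  v <- config$belt_speed
  duration <- attr(schedule, "duration")
  T <- attr(schedule, "cycle_period")
  duty <- attr(schedule, "duty")
  times <- seq(0, duration, by = 1 / fr)
  roles <- limb_roles(config$stim_side)
  mods_for <- function(lb) {
    if (is.null(cycle_mods) || !nrow(cycle_mods)) return(NULL)
    cycle_mods[cycle_mods$limb == lb, , drop = FALSE]
  }
  aep_hind <- v * duty * T / 2
  aep_fore <- 0.28 + v * duty * T / 2
  homolog <- c(ipsi_hind = "contra_hind", contra_hind = "ipsi_hind",
               homo_fore = "diag_fore", diag_fore = "homo_fore")

  # resolve step-length multipliers into AEP values at the touchdown that
  # starts the limb's stimulated cycle, using the trailing (homologous)
  # limb's unmodified closed-form position at that instant
  aep_values <- lapply(setNames(LIMB_ROLES, LIMB_ROLES), function(lb) {
    md <- mods_for(lb)
    if (is.null(md)) return(NULL)
    md <- md[!is.na(md$step_mult), , drop = FALSE]
    if (!nrow(md)) return(NULL)
    base <- if (grepl("hind", lb)) aep_hind else aep_fore
    vals <- vapply(seq_len(nrow(md)), function(r) {
      row <- schedule[schedule$limb == lb & schedule$cycle == md$cycle[r], ]
      t_on <- row$stance_onset
      trail <- toe_traj(schedule, homolog[[lb]], t_on, v, base,
                        animal$swing_apex_hind)
      trail$x + md$step_mult[r] * (base - trail$x)
    }, numeric(1))
    tibble(cycle = md$cycle, value = vals)
  })

  out <- list()
  for (i in seq_len(nrow(roles))) {
    lb <- roles$role[i]; side <- roles$side[i]; girdle <- roles$girdle[i]
    md <- mods_for(lb)
    apex_gains <- if (!is.null(md)) {
      mg <- md[!is.na(md$toe_apex_gain), c("cycle", "toe_apex_gain")]
      names(mg) <- c("cycle", "gain")
      mg
    }
    apex_base <- if (girdle == "hind") animal$swing_apex_hind else
      animal$swing_apex_fore
    aep_base <- if (girdle == "hind") aep_hind else aep_fore
    toe <- toe_traj(schedule, lb, times, v, aep_base, apex_base,
                    aep_values = aep_values[[lb]], apex_gains = apex_gains)
    if (girdle == "hind") {
      flex <- NULL
      if (!is.null(md)) {
        mf <- md[!is.na(md$flex_hip) | !is.na(md$flex_knee) |
                   !is.na(md$flex_ankle), , drop = FALSE]
        if (nrow(mf)) {
          bump <- rep(0, length(times))
          sel <- !toe$stance & toe$cycle %in% mf$cycle
          bump[sel] <- sin(pi * toe$swing_s[sel])^2
          gv <- function(col) {
            z <- mf[[col]][match(toe$cycle, mf$cycle)]
            z[is.na(z)] <- 0
            z * bump
          }
          flex <- list(hip = gv("flex_hip"), knee = gv("flex_knee"),
                       ankle = gv("flex_ankle"))
        }
      }
      ch <- hind_chain(toe$phase, animal, flex = flex)
      lmk <- c("iliac_crest", "trochanter", "knee", "malleolus", "mtp")
      toe_name <- "hind_toe"
    } else {
      ch <- fore_chain(toe$phase, animal)
      lmk <- c("scapula", "humerus", "elbow", "wrist", "mcp")
      toe_name <- "fore_toe"
    }
    part <- c(
      lapply(setNames(lmk, lmk), function(nm)
        tibble(time = times, side = side, landmark = nm,
               x = ch[[nm]]$x, y = ch[[nm]]$y)),
      list(toe = tibble(time = times, side = side, landmark = toe_name,
                        x = toe$x, y = toe$y)))
    out[[lb]] <- bind_rows(part)
  }
  mk <- bind_rows(out) |>
    mutate(frame = as.integer(round(.data$time * fr))) |>
    select("time", "frame", "side", "landmark", "x", "y") |>
    arrange(.data$side, .data$landmark, .data$frame)
  if (min(mk$y) < -0.005)
    abort("kinematic chain penetrates the belt surface (unreachable pose).",
          class = "quadgait_generation_error")
  if (marker_jitter > 0) {
    mk$x <- mk$x + rnorm(nrow(mk), 0, marker_jitter)
    mk$y <- pmax(mk$y + rnorm(nrow(mk), 0, marker_jitter), -0.0049)
  }
  new_markers(mk, frame_rate = fr, belt_speed = v,
              animal_id = animal$animal_id, stim_side = config$stim_side)
}

new_markers <- function(df, frame_rate, belt_speed, animal_id = NA,
                        stim_side = "right") {
  structure(as_tibble(df),
            class = c("marker_trajectories", class(tibble())),
            frame_rate = frame_rate, belt_speed = belt_speed,
            animal_id = animal_id, stim_side = stim_side)
}

#' Synthesize an EMG recording from a footfall schedule
#'
#' Each channel is amplitude-modulated band-limited noise: a phase-gated
#' envelope (flexors SRT/BFP/ST/BB burst during swing, extensors
#' BFA/VL/LG/SOL/TRI/ECU during stance, with 20 ms raised-cosine edges)
#' multiplies a 30--1000 Hz noise carrier normalized to unit mean rectified
#' amplitude, plus an independent baseline noise floor.
#'
#' @inheritParams synthesize_markers
#' @param emg_mods Optional tibble from [inject_stimuli()] (`limb`, `cycle`,
#'   `muscle`, `amp_gain`, `dur_gain`).
#' @param channels Tibble with columns `side`, `muscle`, or `NULL` for all
#'   ten muscles bilaterally.
#' @return A tibble of class `emg_recording` with columns `time`, `side`,
#'   `muscle`, `value` and attributes `rate`, `animal_id`.
#' @export
synthesize_emg <- function(schedule, animal, config, emg_mods = NULL,
                           channels = NULL) {
  rate <- config$emg_rate
  duration <- attr(schedule, "duration")
  times <- seq(0, duration, by = 1 / rate)
  n <- length(times)
  roles <- limb_roles(config$stim_side)
  if (is.null(channels))
    channels <- tidyr::expand_grid(side = c("left", "right"),
                                   muscle = ALL_MUSCLES)
  if (!all(channels$muscle %in% ALL_MUSCLES))
    abort(paste0("unknown muscle: ",
                 paste(setdiff(channels$muscle, ALL_MUSCLES), collapse = ", ")),
          class = "quadgait_param_error")
  ramp <- 0.020
  bp <- emg_bandpass_coeffs(rate)
  out <- vector("list", nrow(channels))
  for (i in seq_len(nrow(channels))) {
    side <- channels$side[i]; mus <- channels$muscle[i]
    girdle <- if (mus %in% FORE_MUSCLES) "fore" else "hind"
    lb <- roles$role[roles$side == side & roles$girdle == girdle]
    rows <- schedule[schedule$limb == lb, , drop = FALSE]
    env <- numeric(n)
    base_amp <- animal$emg_amp[[mus]]
    md <- NULL
    if (!is.null(emg_mods) && nrow(emg_mods))
      md <- emg_mods[emg_mods$limb == lb & emg_mods$muscle == mus, ,
                     drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      if (mus %in% FLEXOR_MUSCLES) {
        a <- rows$stance_offset[r]; b <- rows$next_onset[r]
      } else {
        a <- rows$stance_onset[r]; b <- rows$stance_offset[r]
      }
      amp <- base_amp; dg <- 1
      if (!is.null(md) && nrow(md)) {
        j <- which(md$cycle == rows$cycle[r])
        if (length(j)) {
          amp <- amp * md$amp_gain[j[1]]
          dg <- md$dur_gain[j[1]]
        }
      }
      half <- (b - a) / 2 * dg
      ctr <- (a + b) / 2
      a2 <- ctr - half; b2 <- ctr + half
      i0 <- max(1L, ceiling(a2 * rate) + 1L)
      i1 <- min(n, floor(b2 * rate) + 1L)
      if (i1 <= i0) next
      tt <- times[i0:i1]
      g <- rep(1, length(tt))
      le <- tt < a2 + ramp
      g[le] <- 0.5 * (1 - cos(pi * (tt[le] - a2) / ramp))
      re <- tt > b2 - ramp
      g[re] <- 0.5 * (1 - cos(pi * (b2 - tt[re]) / ramp))
      env[i0:i1] <- env[i0:i1] + amp * g
    }
    carrier <- signal::filtfilt(bp, rnorm(n))
    carrier <- carrier / mean(abs(carrier))
    floor_noise <- signal::filtfilt(bp, rnorm(n))
    floor_noise <- floor_noise / mean(abs(floor_noise))
    value <- env * carrier +
      animal$noise$emg_noise * base_amp * floor_noise
    out[[i]] <- tibble(time = times, side = side, muscle = mus,
                       value = value)
  }
  structure(bind_rows(out),
            class = c("emg_recording", class(tibble())),
            rate = rate, animal_id = animal$animal_id,
            stim_side = config$stim_side)
}

emg_bandpass_coeffs <- function(rate, low = 30, high = 1000, order = 4) {
  if (rate <= 2 * high)
    abort("sampling rate too low for the upper band edge.",
          class = "quadgait_param_error")
  signal::butter(order / 2, c(low, high) / (rate / 2), type = "pass")
}

#' Inject phase-targeted stimuli into a schedule
#'
#' Chooses stimulated ipsilateral cycles every 5--6 cycles (configurable),
#' assigns each stimulus a target phase, regenerates the affected cycles
#' from the phase's [perturbation_profile()] and computes the stimulus
#' onset at the target normalized phase of the realized (perturbed) cycle.
#' Temporal multipliers move the limb's stance offset and next onset; the
#' following cycle absorbs the shift so later cycles stay phase-locked.
#' Support-period multipliers (relative to the control window) move the
#' event terminating the target period, pushing member-limb offsets that
#' would otherwise create a less-than-two-limb support.
#'
#' @param schedule A `footfall_schedule`.
#' @param config A [session_config()].
#' @param profiles Named list of phase profiles; defaults to the config's.
#' @return A list with elements `schedule` (perturbed), `stimuli` (tibble:
#'   `stim_id`, `onset`, `side`, `phase_target`, `ipsi_cycle`, `train`),
#'   `cycle_mods`, `emg_mods` and `truth` (tibble of injected multipliers:
#'   `stim_id`, `phase`, `variable`, `target`, `multiplier`).
#' @export
inject_stimuli <- function(schedule, config,
                           profiles = config$perturbation_profiles) {
  n_cyc <- attr(schedule, "n_cycles")
  T <- attr(schedule, "cycle_period")
  n_stim <- length(config$phase_targets) * config$stimuli_per_phase
  phases <- sample(rep(config$phase_targets,
                       each = config$stimuli_per_phase))
  rng <- config$stim_every_cycles
  k <- 1L
  cycles <- integer(n_stim)
  for (i in seq_len(n_stim)) {
    step <- if (rng[1] == rng[2]) rng[1] else
      sample(seq(rng[1], rng[2]), 1L)
    k <- k + step
    cycles[i] <- k
  }
  if (any(cycles > n_cyc - 1L))
    abort("requested stimuli exceed the cycles available at the configured spacing.",
          class = "quadgait_scheduling_error")
  stim <- vector("list", n_stim)
  cmods <- list(); emods <- list(); truths <- list()
  for (i in seq_len(n_stim)) {
    p <- phases[i]
    prof <- profiles[[p]]
    if (is.null(prof)) prof <- perturbation_profile()
    res <- apply_perturbation(schedule, cycles[i], p, prof, config, i)
    schedule <- res$schedule
    stim[[i]] <- tibble(stim_id = i, onset = res$onset,
                        side = config$stim_side, phase_target = p,
                        ipsi_cycle = cycles[i])
    cmods[[i]] <- res$cycle_mods
    emods[[i]] <- res$emg_mods
    truths[[i]] <- res$truth
  }
  list(schedule = schedule,
       stimuli = bind_rows(stim),
       cycle_mods = bind_rows(cmods),
       emg_mods = bind_rows(emods),
       truth = bind_rows(truths))
}

apply_temporal <- function(schedule, limb, cyc_idx, m_sw = 1, m_cy = NULL) {
  row <- schedule[schedule$limb == limb & schedule$cycle == cyc_idx, ]
  cyc <- row$next_onset - row$stance_onset
  sw <- row$next_onset - row$stance_offset
  if (!is.null(m_cy)) {
    new_next <- row$stance_onset + cyc * m_cy
    new_off <- new_next - sw * m_sw
  } else {
    new_next <- row$stance_offset + sw * m_sw
    new_off <- row$stance_offset
  }
  schedule_set_events(schedule, limb, cyc_idx,
                      stance_offset = new_off, next_onset = new_next)
}

apply_perturbation <- function(schedule, k, phase, prof, config, stim_id) {
  T <- attr(schedule, "cycle_period")
  pick <- function(v, nm, default = NULL)
    if (nm %in% names(v)) v[[nm]] else default
  truth <- list(); cmods <- list(); emods <- list()
  add_truth <- function(variable, target, mult)
    truth[[length(truth) + 1L]] <<- tibble(
      stim_id = stim_id, phase = phase, variable = variable,
      target = target, multiplier = mult)

  # 1. ipsilateral temporal effects
  m_sw_i <- pick(prof$swing_multiplier, "ipsi_hind", 1)
  m_cy_i <- pick(prof$cycle_multiplier, "ipsi_hind")
  if (m_sw_i != 1 || !is.null(m_cy_i)) {
    schedule <- apply_temporal(schedule, "ipsi_hind", k, m_sw_i, m_cy_i)
    if (m_sw_i != 1) add_truth("swing_duration", "ipsi_hind", m_sw_i)
    if (!is.null(m_cy_i)) add_truth("cycle_duration", "ipsi_hind", m_cy_i)
  }

  # 2. stimulus onset at the target phase of the realized ipsilateral cycle
  irow <- schedule[schedule$limb == "ipsi_hind" & schedule$cycle == k, ]
  stance <- irow$stance_offset - irow$stance_onset
  swing <- irow$next_onset - irow$stance_offset
  pj <- config$phase_jitter
  u <- function(a, b) if (b > a) runif(1, a, b) else a
  onset <- switch(phase,
    mid_stance = irow$stance_onset + u(0.5 - pj, 0.5 + pj) * stance,
    stance_to_swing = irow$stance_offset + u(0.01, 0.01 + pj) * swing,
    mid_swing = irow$stance_offset + u(0.5 - pj, 0.5 + pj) * swing,
    swing_to_stance = irow$stance_offset +
      u(0.95 - pj / 2, min(0.95 + pj / 2, 0.99)) * swing)

  # 3. temporal effects on the other limbs' cycles containing the stimulus
  for (lb in setdiff(LIMB_ROLES, "ipsi_hind")) {
    m_sw <- pick(prof$swing_multiplier, lb, 1)
    m_cy <- pick(prof$cycle_multiplier, lb)
    if (m_sw == 1 && is.null(m_cy)) next
    j <- schedule_cycle_at(schedule, lb, onset)
    if (is.na(j)) next
    schedule <- apply_temporal(schedule, lb, j, m_sw, m_cy)
    if (m_sw != 1) add_truth("swing_duration", lb, m_sw)
    if (!is.null(m_cy)) add_truth("cycle_duration", lb, m_cy)
  }

  # 4. support-period multipliers (relative to the nominal control geometry)
  if (length(prof$support_multiplier)) {
    irow <- schedule[schedule$limb == "ipsi_hind" & schedule$cycle == k, ]
    for (cat in names(prof$support_multiplier)) {
      m <- prof$support_multiplier[[cat]]
      res <- apply_support_target(schedule, cat, m,
                                  ws = irow$stance_onset,
                                  we = irow$next_onset, T = T,
                                  duty = attr(schedule, "duty"),
                                  offsets = attr(schedule, "phase_offsets"))
      schedule <- res$schedule
      add_truth("support", cat, res$realized)
    }
  }

  # 5. spatial and EMG modifications consumed by the synthesizers
  if (prof$toe_height_gain != 1 || length(prof$joint_flexion_delta)) {
    cmods[[length(cmods) + 1L]] <- tibble(
      limb = "ipsi_hind", cycle = k,
      toe_apex_gain = if (prof$toe_height_gain != 1)
        prof$toe_height_gain else NA_real_,
      step_mult = NA_real_,
      flex_hip = pick(prof$joint_flexion_delta, "hip", NA_real_),
      flex_knee = pick(prof$joint_flexion_delta, "knee", NA_real_),
      flex_ankle = pick(prof$joint_flexion_delta, "ankle", NA_real_))
    if (prof$toe_height_gain != 1)
      add_truth("toe_height", "ipsi_hind", prof$toe_height_gain)
  }
  for (lb in names(prof$step_length_multiplier)) {
    j <- schedule_cycle_at(schedule, lb, onset)
    if (is.na(j)) next
    cmods[[length(cmods) + 1L]] <- tibble(
      limb = lb, cycle = j,
      toe_apex_gain = NA_real_,
      step_mult = prof$step_length_multiplier[[lb]],
      flex_hip = NA_real_, flex_knee = NA_real_, flex_ankle = NA_real_)
    add_truth("step_length", lb, prof$step_length_multiplier[[lb]])
  }
  emg_names <- union(names(prof$emg_amplitude_gain),
                     names(prof$emg_duration_gain))
  for (nm in emg_names) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !(parts[1] %in% LIMB_ROLES) ||
        !(parts[2] %in% ALL_MUSCLES))
      abort(paste0("EMG gain name must be '<role>.<muscle>': ", nm),
            class = "quadgait_config_error")
    j <- schedule_cycle_at(schedule, parts[1], onset)
    if (is.na(j)) next
    ag <- pick(prof$emg_amplitude_gain, nm, 1)
    dg <- pick(prof$emg_duration_gain, nm, 1)
    emods[[length(emods) + 1L]] <- tibble(
      limb = parts[1], cycle = j, muscle = parts[2],
      amp_gain = ag, dur_gain = dg)
    if (ag != 1) add_truth("emg_amplitude", nm, ag)
    if (dg != 1) add_truth("emg_duration", nm, dg)
  }

  list(schedule = schedule, onset = onset,
       cycle_mods = bind_rows(cmods), emg_mods = bind_rows(emods),
       truth = bind_rows(truth))
}

# Nominal (jitter-free) support-category durations of one cycle, from the
# animal's duty factor and limb phase offsets.
nominal_support_durations <- function(T, duty, offsets) {
  iv <- bind_rows(lapply(LIMB_ROLES, function(lb) {
    on <- (offsets[[lb]] + (-2:1)) * T
    tibble(limb = lb, onset = on, offset = on + duty * T)
  }))
  support_category_durations(iv, 0, T)
}

# Scale the duration of one support category in the stimulated window to
# `m` times its nominal control-cycle duration by moving the schedule
# event that terminates the (first) period of that category. Returns the
# perturbed schedule and the realized multiplier (capped at the window
# edge when the target would overrun the cycle).
apply_support_target <- function(schedule, cat, m, ws, we, T, duty,
                                 offsets) {
  stv <- schedule_stance_intervals(schedule)
  d_ref <- nominal_support_durations(T, duty, offsets) |>
    filter(.data$category == cat) |>
    pull("duration")
  if (d_ref <= 0)
    abort(paste0("support target category absent from the nominal cycle: ",
                 cat), class = "quadgait_param_error")
  per <- support_periods(stv, ws, we)
  rows <- per[per$category == cat, , drop = FALSE]
  if (nrow(rows) == 0)
    abort(paste0("support target category absent from stimulated cycle: ",
                 cat), class = "quadgait_param_error")
  p1 <- rows[1L, ]
  others <- sum(rows$duration) - p1$duration
  new_end <- min(p1$start + (m * d_ref - others), we - 1e-9)
  if (new_end <= p1$start + 1e-9)
    abort("support multiplier not achievable within the stimulated cycle.",
          class = "quadgait_param_error")
  realized <- (new_end - p1$start + others) / d_ref
  # pushed events sit several frames past the new boundary so that
  # detection noise cannot reorder them and split the period
  guard <- 0.05 * T
  members <- strsplit(p1$limbs, "+", fixed = TRUE)[[1]]
  tol <- 1e-9
  old_end <- p1$end
  # the terminating event: a non-member onset or a member offset at old_end
  moved <- FALSE
  for (lb in setdiff(LIMB_ROLES, members)) {
    i <- which(schedule$limb == lb &
                 abs(schedule$stance_onset - old_end) < tol)
    if (length(i) == 1) {
      schedule <- schedule_set_events(schedule, lb, schedule$cycle[i],
                                      stance_onset = new_end)
      moved <- TRUE
      moved_limb <- lb
      break
    }
  }
  if (!moved) {
    for (lb in members) {
      i <- which(schedule$limb == lb &
                   abs(schedule$stance_offset - old_end) < tol)
      if (length(i) == 1) {
        schedule <- schedule_set_events(schedule, lb, schedule$cycle[i],
                                        stance_offset = new_end)
        moved <- TRUE
        moved_limb <- lb
        break
      }
    }
  }
  if (!moved)
    abort("could not identify the event terminating the support period.",
          class = "quadgait_param_error")
  # push events that would fall inside the extended period
  if (new_end > old_end) {
    g <- guard
    for (lb in setdiff(LIMB_ROLES, moved_limb)) {
      sub <- which(schedule$limb == lb)
      off_in <- sub[schedule$stance_offset[sub] > old_end - tol &
                      schedule$stance_offset[sub] < new_end &
                      lb %in% members]
      for (ii in off_in) {
        schedule <- schedule_set_events(schedule, lb, schedule$cycle[ii],
                                        stance_offset = new_end + g)
        g <- g + guard
      }
      on_in <- sub[schedule$stance_onset[sub] > old_end + tol &
                     schedule$stance_onset[sub] < new_end &
                     !(lb %in% members)]
      for (ii in on_in) {
        schedule <- schedule_set_events(schedule, lb, schedule$cycle[ii],
                                        stance_onset = new_end + g)
        g <- g + guard
      }
    }
  }
  list(schedule = schedule, realized = realized)
}

#' Simulate one animal's session
#'
#' @param config A [session_config()].
#' @param animal_id Animal identifier.
#' @param emg_channels Tibble (`side`, `muscle`) of EMG channels to
#'   synthesize, `NULL` for all, or `FALSE` to skip EMG.
#' @param markers If `FALSE`, skip marker synthesis (schedule-level
#'   session).
#' @return A list of class `gait_session`: `config`, `animal`, `schedule`,
#'   `stimuli`, `truth`, `cycle_mods`, `emg_mods`, `markers`, `emg`.
#' @export
simulate_session <- function(config, animal_id = 1L, emg_channels = FALSE,
                             markers = TRUE) {
  animal <- animal_params(config, animal_id)
  schedule <- build_footfall_schedule(animal, config$cycles_per_animal,
                                      frame_rate = config$frame_rate)
  inj <- inject_stimuli(schedule, config)
  mk <- NULL
  if (isTRUE(markers))
    mk <- synthesize_markers(inj$schedule, animal, config, inj$cycle_mods)
  emg <- NULL
  if (!isFALSE(emg_channels))
    emg <- synthesize_emg(inj$schedule, animal, config, inj$emg_mods,
                          channels = if (is.null(emg_channels)) NULL else
                            emg_channels)
  structure(list(config = config, animal = animal,
                 schedule = inj$schedule, stimuli = inj$stimuli,
                 truth = inj$truth, cycle_mods = inj$cycle_mods,
                 emg_mods = inj$emg_mods, markers = mk, emg = emg),
            class = "gait_session")
}

#' Simulate a multi-animal study
#'
#' Seeds the generator from `config$seed` (fixed seed, byte-identical
#' output) and simulates `config$n_animals` sessions.
#'
#' @inheritParams simulate_session
#' @return A list of `gait_session` objects, class `gait_study`.
#' @export
simulate_study <- function(config, emg_channels = FALSE, markers = TRUE) {
  set.seed(config$seed)
  sessions <- lapply(seq_len(config$n_animals), function(i)
    simulate_session(config, animal_id = i, emg_channels = emg_channels,
                     markers = markers))
  structure(sessions, class = "gait_study")
}
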