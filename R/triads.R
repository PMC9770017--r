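#' Phase-window configuration
#'
#' The four phases partition (part of) the normalized cycle: mid-stance and
#' mid-swing are centered windows on the stance and swing fractions, the
#' two transitions are bands of half-width `transition` around stance
#' offset and stance onset. Stimuli falling outside every window are
#' excluded. Windows must be mutually disjoint.
#'
#' @param mid Length-2 numeric, the `[lo, hi]` window on the sub-phase
#'   fraction for mid-stance and mid-swing.
#' @param transition Half-width (fraction of the sub-phase) of the
#'   transition windows.
#' @return Named list of class `phase_windows`.
#' @export
phase_windows <- function(mid = c(0.3, 0.7), transition = 0.1) {
  if (length(mid) != 2 || mid[1] >= mid[2])
    abort("`mid` must be an increasing [lo, hi] pair.",
          class = "quadgait_config_error")
  if (transition <= 0 || mid[1] < transition || mid[2] > 1 - transition)
    abort("phase windows overlap: mid window must lie inside the transition bands.",
          class = "quadgait_config_error")
  structure(list(mid = mid, transition = transition),
            class = "phase_windows")
}

#' Normalized phase of a stimulus within its ipsilateral cycle
#'
#' @param onset Stimulus onset time (s).
#' @param cycle One-row cycle tibble (see [build_cycles()]).
#' @return A list with `phase` (fraction of the cycle in `[0, 1)`),
#'   `stance_fraction` (fraction of stance, `NA` during swing) and
#'   `swing_fraction` (fraction of swing, `NA` during stance).
#' @export
normalized_phase <- function(onset, cycle) {
  if (onset < cycle$stance_onset || onset >= cycle$next_onset)
    abort("stimulus onset lies outside the cycle.",
          class = "quadgait_assignment_error")
  phase <- (onset - cycle$stance_onset) / cycle$cycle_duration
  in_stance <- onset < cycle$stance_offset
  list(
    phase = phase,
    stance_fraction = if (in_stance)
      (onset - cycle$stance_onset) / cycle$stance_duration else NA_real_,
    swing_fraction = if (!in_stance)
      (onset - cycle$stance_offset) / cycle$swing_duration else NA_real_)
}

#' Classify a stimulus into one of the four phases
#'
#' @param stance_fraction,swing_fraction Normalized sub-phase fractions
#'   (exactly one non-`NA`), see [normalized_phase()].
#' @param windows A [phase_windows()].
#' @return One of `"mid_stance"`, `"stance_to_swing"`, `"mid_swing"`,
#'   `"swing_to_stance"` or `"excluded"`.
#' @export
classify_phase <- function(stance_fraction, swing_fraction,
                           windows = phase_windows()) {
  w <- windows
  if (!is.na(stance_fraction)) {
    f <- stance_fraction
    if (f < w$transition) return("swing_to_stance")
    if (f > 1 - w$transition) return("stance_to_swing")
    if (f >= w$mid[1] && f <= w$mid[2]) return("mid_stance")
    return("excluded")
  }
  f <- swing_fraction
  if (f < w$transition) return("stance_to_swing")
  if (f > 1 - w$transition) return("swing_to_stance")
  if (f >= w$mid[1] && f <= w$mid[2]) return("mid_swing")
  "excluded"
}

#' Extract control/stimulated/post cycle triads
#'
#' For each stimulus, the stimulated cycle of every limb is the limb's own
#' cycle containing the stimulus onset; the control and post cycles are the
#' immediately preceding and following cycles of that limb. A triad is
#' invalid when the stimulus phase is excluded, when any limb lacks three
#' consecutive complete cycles, or when another stimulus falls within the
#' ipsilateral triad span.
#'
#' @param stimuli Tibble with columns `stim_id`, `onset` (and optionally
#'   `phase_target`).
#' @param cycles Cycle tibble for the four limb roles ([detect_cycles()]).
#' @param windows A [phase_windows()].
#' @return A tibble of class `cycle_triads`, one row per stimulus and limb:
#'   `stim_id`, `onset`, `phase`, `valid`, `reason`, `limb`,
#'   `control_cycle`, `stim_cycle`, `post_cycle` (cycle indices).
#' @export
extract_triads <- function(stimuli, cycles, windows = phase_windows()) {
  if (nrow(stimuli) == 0) return(empty_triads())
  ipsi <- cycles |> filter(.data$limb == "ipsi_hind")
  res <- lapply(seq_len(nrow(stimuli)), function(i) {
    t0 <- stimuli$onset[i]
    sid <- stimuli$stim_id[i]
    ir <- ipsi |> filter(.data$stance_onset <= t0, t0 < .data$next_onset)
    if (nrow(ir) != 1) {
      warn(sprintf("stimulus %s: no ipsilateral cycle contains the onset; skipped.",
                   sid))
      return(triad_rows(sid, t0, "excluded", FALSE, "no_ipsi_cycle"))
    }
    np <- normalized_phase(t0, ir)
    phase <- classify_phase(np$stance_fraction, np$swing_fraction, windows)
    if (phase == "excluded")
      return(triad_rows(sid, t0, phase, FALSE, "phase_excluded"))
    others <- stimuli$onset[stimuli$stim_id != sid]
    ctl <- ipsi |> filter(.data$cycle == ir$cycle - 1L)
    pst <- ipsi |> filter(.data$cycle == ir$cycle + 1L)
    if (nrow(ctl) == 1 && nrow(pst) == 1 &&
        any(others >= ctl$stance_onset & others < pst$next_onset))
      return(triad_rows(sid, t0, phase, FALSE, "stimulus_collision"))
    rows <- lapply(LIMB_ROLES, function(lb) {
      sub <- cycles |> filter(.data$limb == lb)
      j <- sub$cycle[sub$stance_onset <= t0 & t0 < sub$next_onset]
      if (length(j) != 1) return(NULL)
      trip <- sub |> filter(.data$cycle %in% (j + (-1L:1L)))
      if (nrow(trip) != 3) return(NULL)
      tibble(limb = lb, control_cycle = j - 1L, stim_cycle = j,
             post_cycle = j + 1L)
    })
    if (any(vapply(rows, is.null, logical(1))))
      return(triad_rows(sid, t0, phase, FALSE, "incomplete_cycles"))
    bind_rows(rows) |>
      mutate(stim_id = sid, onset = t0, phase = phase, valid = TRUE,
             reason = NA_character_, .before = 1L)
  })
  out <- bind_rows(res)
  structure(out, class = c("cycle_triads", class(tibble())))
}

triad_rows <- function(sid, t0, phase, valid, reason) {
  tibble(stim_id = sid, onset = t0, phase = phase, valid = valid,
         reason = reason, limb = NA_character_,
         control_cycle = NA_integer_, stim_cycle = NA_integer_,
         post_cycle = NA_integer_)
}

empty_triads <- function() {
  structure(triad_rows(integer(0), numeric(0), character(0), logical(0),
                       character(0)),
            class = c("cycle_triads", class(tibble())))
}
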