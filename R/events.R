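#' Event detection parameters
#'
#' Contact is defined by toe-height thresholding with a persistence rule
#' (the original scoring was visual; this is an explicit, configurable
#' stand-in): a frame is in contact when toe height is below
#' `height_threshold` and the condition persists for at least
#' `min_contact` frames. Stance offset is the most caudal toe position
#' within each stance run. Events are reported on the video frame grid.
#'
#' @param height_threshold Contact height threshold (m).
#' @param min_contact Minimum contact run length (frames).
#' @param smooth_x_hz Optional zero-phase low-pass cutoff (Hz) applied to
#'   toe x before the most-caudal search. Default `NULL` (raw): the belt
#'   carries the paw backward steeply during stance, so the minimum is
#'   well conditioned, and smoothing the asymmetric corner at liftoff
#'   would bias the offset toward the flat swing side.
#' @return Named list of class `event_params`.
#' @export
event_params <- function(height_threshold = 0.005, min_contact = 3L,
                         smooth_x_hz = NULL) {
  if (height_threshold <= 0 || min_contact < 1)
    abort("invalid event detection parameters.",
          class = "quadgait_param_error")
  structure(list(height_threshold = height_threshold,
                 min_contact = as.integer(min_contact),
                 smooth_x_hz = smooth_x_hz),
            class = "event_params")
}

#' Detect stance onsets from a toe trajectory
#'
#' An onset is the first frame of each maximal contact run (preceded by a
#' non-contact frame, so a record entirely in contact yields no onset).
#'
#' @param time Frame times (s), uniformly sampled.
#' @param y Toe height above the belt (m).
#' @param params An [event_params()].
#' @return Numeric vector of onset times (on the frame grid).
#' @export
detect_stance_onsets <- function(time, y, params = event_params()) {
  if (length(time) < 2)
    abort("trajectory must span at least 2 frames.",
          class = "quadgait_input_error")
  if (any(!is.finite(y)))
    abort("toe trajectory contains non-finite values.",
          class = "quadgait_input_error")
  contact <- y < params$height_threshold
  r <- rle(contact)
  keep <- r$values & r$lengths >= params$min_contact
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- starts[keep]
  idx <- idx[idx > 1L]  # need an observed swing-to-stance transition
  time[idx]
}

#' Detect stance offsets (most caudal toe position per stance run)
#'
#' For each consecutive onset pair, the offset is the time of the minimum
#' of toe x within `[onset, next onset)` -- the most caudal point, since
#' the paw travels backward with the belt during stance. A cycle whose
#' minimum falls on the interval's last frame has no observed swing and is
#' excluded (offset `NA`).
#'
#' @param time Frame times (s).
#' @param x Toe position along the direction of travel (m).
#' @param onsets Onset times from [detect_stance_onsets()].
#' @param params An [event_params()].
#' @return Numeric vector of length `length(onsets) - 1` with offset times
#'   (`NA` where undefined).
#' @export
detect_stance_offsets <- function(time, x, onsets, params = event_params()) {
  if (length(onsets) == 0)
    abort("no onsets supplied.", class = "quadgait_input_error")
  if (!is.null(params$smooth_x_hz)) {
    fr <- 1 / median(diff(time))
    x <- lowpass_series(x, fr, params$smooth_x_hz)
  }
  n <- length(onsets)
  if (n < 2) return(numeric(0))
  vapply(seq_len(n - 1L), function(i) {
    sel <- which(time >= onsets[i] & time < onsets[i + 1L])
    if (length(sel) < 3) return(NA_real_)
    xs <- x[sel]
    jm <- which.min(xs)
    if (jm == length(sel) || jm == 1L) return(NA_real_)
    # Early swing advances the toe very slowly, so under tracking noise
    # the raw argmin drifts into the swing by an amount that grows with
    # swing duration. Take the earliest sample statistically
    # indistinguishable from the minimum; the noise scale comes from the
    # residuals of a line fitted to the stance portion, where belt-driven
    # toe motion is exactly linear (zero for noiseless data, so the raw
    # minimum is returned unchanged).
    ns <- max(3L, floor(0.8 * jm))
    tt <- time[sel][1:ns]
    res <- stats::lm.fit(cbind(1, tt), xs[1:ns])$residuals
    tau <- 2 * sqrt(mean(res^2))
    j <- sel[which(xs <= xs[jm] + tau)[1L]]
    if (j == sel[length(sel)] || j == sel[1L]) return(NA_real_)
    time[j]
  }, numeric(1))
}

# Zero-phase Butterworth low-pass (2nd order, applied forward and backward).
lowpass_series <- function(v, rate, cutoff) {
  if (is.null(cutoff) || cutoff >= rate / 2) return(v)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, v))
}

#' Assemble gait cycles from paired events
#'
#' One cycle per consecutive onset pair, with cycle duration from
#' successive stance onsets, stance duration from onset to offset, and
#' swing duration as cycle minus stance (exact by construction).
#'
#' @param onsets Onset times (s), increasing.
#' @param offsets Offset times, one per onset pair (possibly `NA`).
#' @param limb Limb label attached to the cycles.
#' @return Tibble with columns `limb`, `cycle`, `stance_onset`,
#'   `stance_offset`, `next_onset`, `cycle_duration`, `stance_duration`,
#'   `swing_duration`. Cycles with missing offsets are dropped.
#' @export
build_cycles <- function(onsets, offsets, limb = "limb") {
  n <- length(onsets)
  if (n < 2) return(empty_cycles())
  if (length(offsets) != n - 1L)
    abort("expected one offset per consecutive onset pair.",
          class = "quadgait_pairing_error")
  ok <- !is.na(offsets)
  bad <- ok & (offsets <= onsets[-n] | offsets >= onsets[-1L])
  if (any(bad))
    abort(sprintf(
      "event interleaving violated at onset %.6f / offset %.6f.",
      onsets[-n][bad][1], offsets[bad][1]),
      class = "quadgait_pairing_error")
  tibble(limb = limb, cycle = seq_len(n - 1L),
         stance_onset = onsets[-n], stance_offset = offsets,
         next_onset = onsets[-1L]) |>
    filter(!is.na(.data$stance_offset)) |>
    mutate(cycle_duration = .data$next_onset - .data$stance_onset,
           stance_duration = .data$stance_offset - .data$stance_onset,
           swing_duration = .data$cycle_duration - .data$stance_duration)
}

empty_cycles <- function() {
  tibble(limb = character(), cycle = integer(), stance_onset = numeric(),
         stance_offset = numeric(), next_onset = numeric(),
         cycle_duration = numeric(), stance_duration = numeric(),
         swing_duration = numeric())
}

#' Detect gait cycles for all four limbs from marker trajectories
#'
#' Runs onset/offset detection on each limb's toe trajectory and assembles
#' per-limb cycle tables, labeled by limb role relative to the stimulated
#' hindlimb.
#'
#' @param markers A `marker_trajectories` tibble (see
#'   [synthesize_markers()] / [read_marker_csv()]).
#' @param stim_side Side of the stimulated hindlimb; defaults to the
#'   markers' attribute.
#' @param params An [event_params()].
#' @return Tibble of cycles (see [build_cycles()]) for the four limb roles.
#' @export
detect_cycles <- function(markers, stim_side = NULL,
                          params = event_params()) {
  stim_side <- stim_side %||% attr(markers, "stim_side") %||% "right"
  roles <- limb_roles(stim_side)
  out <- lapply(seq_len(nrow(roles)), function(i) {
    toe_name <- if (roles$girdle[i] == "hind") "hind_toe" else "fore_toe"
    tr <- markers |>
      filter(.data$side == roles$side[i], .data$landmark == toe_name) |>
      arrange(.data$time)
    if (nrow(tr) == 0) return(empty_cycles())
    onsets <- detect_stance_onsets(tr$time, tr$y, params)
    if (length(onsets) < 2) return(empty_cycles())
    offsets <- detect_stance_offsets(tr$time, tr$x, onsets, params)
    build_cycles(onsets, offsets, limb = roles$role[i])
  })
  bind_rows(out)
}
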