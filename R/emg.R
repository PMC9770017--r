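#' Band-pass filter an EMG channel
#'
#' Zero-phase Butterworth band-pass (order 4 after forward-backward
#' application), 30--1000 Hz by default.
#'
#' @param values Raw EMG samples.
#' @param rate Sampling rate (Hz); must exceed twice the upper cutoff.
#' @param low,high Band edges (Hz).
#' @return Filtered signal.
#' @export
bandpass_emg <- function(values, rate, low = 30, high = 1000) {
  bf <- emg_bandpass_coeffs(rate, low, high)
  as.numeric(signal::filtfilt(bf, values))
}

#' Rectified low-pass envelope of a filtered EMG channel
#'
#' Full-wave rectification followed by a zero-phase Butterworth low-pass.
#'
#' @param filtered Band-passed EMG samples.
#' @param rate Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz).
#' @return Envelope series (same length).
#' @export
emg_envelope <- function(filtered, rate, cutoff = 50) {
  lowpass_series(abs(filtered), rate, cutoff)
}

#' Burst-detector parameters
#'
#' @param k Upper threshold is baseline median + `k` * MAD; the lower
#'   threshold uses `k / 2`.
#' @param min_duration Minimum time (s) above/below threshold to open or
#'   close a burst.
#' @param envelope_hz Envelope low-pass cutoff (Hz).
#' @return Named list of class `burst_params`.
#' @export
burst_params <- function(k = 3, min_duration = 0.02, envelope_hz = 50) {
  structure(list(k = k, min_duration = min_duration,
                 envelope_hz = envelope_hz), class = "burst_params")
}

# Baseline statistics (median + MAD) over the record excluding detected
# bursts, iterated twice for robustness to burst contamination.
burst_thresholds <- function(env, rate, params) {
  stat <- function(sel) {
    m <- median(env[sel]); s <- mad(env[sel])
    c(lo = m + params$k / 2 * s, hi = m + params$k * s)
  }
  # seed from the lower quartile: bursts may occupy most of the record
  # (extensors at high duty factors), which would drag the global median
  # into the burst level
  th <- stat(env <= quantile(env, 0.25))
  for (pass in 1:2) {
    b <- burst_runs(env, th[["hi"]], th[["lo"]], rate, params$min_duration)
    excl <- rep(FALSE, length(env))
    for (r in seq_len(nrow(b))) excl[b$i0[r]:b$i1[r]] <- TRUE
    if (all(excl)) break
    th <- stat(!excl)
  }
  th
}

# Double-threshold state machine: a burst opens after >= min_duration
# above the upper threshold and closes after >= min_duration below the
# lower threshold.
burst_runs <- function(env, hi, lo, rate, min_duration) {
  min_n <- max(1L, round(min_duration * rate))
  above_hi <- env > hi
  below_lo <- env < lo
  r_hi <- rle(above_hi)
  ends_hi <- cumsum(r_hi$lengths)
  starts_hi <- ends_hi - r_hi$lengths + 1L
  cand <- starts_hi[r_hi$values & r_hi$lengths >= min_n]
  r_lo <- rle(below_lo)
  ends_lo <- cumsum(r_lo$lengths)
  starts_lo <- ends_lo - r_lo$lengths + 1L
  closers <- starts_lo[r_lo$values & r_lo$lengths >= min_n]
  i0 <- integer(); i1 <- integer()
  pos <- 0L
  for (s in cand) {
    if (s <= pos) next
    nxt <- closers[closers > s]
    e <- if (length(nxt)) nxt[1] - 1L else length(env)
    i0 <- c(i0, s); i1 <- c(i1, e)
    pos <- e
  }
  tibble(i0 = i0, i1 = i1)
}

#' Detect EMG bursts within cycle windows
#'
#' Double-threshold detection on the envelope (open above median + k*MAD,
#' close below median + k/2*MAD, both with a persistence requirement); at
#' most one burst -- the longest -- is retained per window, matching
#' one-burst-per-cycle reporting.
#'
#' @param envelope Envelope series ([emg_envelope()]).
#' @param time Sample times (s).
#' @param windows Tibble with columns `start`, `end` (one row per cycle).
#' @param params A [burst_params()].
#' @return Tibble with one row per window: `start`, `end`, `onset`,
#'   `offset` (`NA` when no burst), `full_window` (quality flag set when
#'   the envelope never drops below threshold).
#' @export
detect_bursts <- function(envelope, time, windows,
                          params = burst_params()) {
  rate <- 1 / median(diff(time))
  th <- burst_thresholds(envelope, rate, params)
  runs <- burst_runs(envelope, th[["hi"]], th[["lo"]], rate,
                     params$min_duration)
  runs$t0 <- time[runs$i0]; runs$t1 <- time[runs$i1]
  out <- lapply(seq_len(nrow(windows)), function(i) {
    ws <- windows$start[i]; we <- windows$end[i]
    ov0 <- pmax(runs$t0, ws); ov1 <- pmin(runs$t1, we)
    ov <- ov1 - ov0
    j <- which(ov > 0)
    if (length(j) == 0)
      return(tibble(start = ws, end = we, onset = NA_real_,
                    offset = NA_real_, full_window = FALSE))
    j <- j[which.max(ov[j])]
    full <- runs$t0[j] <= ws && runs$t1[j] >= we
    tibble(start = ws, end = we,
           onset = max(runs$t0[j], ws), offset = min(runs$t1[j], we),
           full_window = full)
  })
  bind_rows(out)
}

#' Burst metrics: duration and mean rectified amplitude
#'
#' Mean amplitude is the integral of the full-wave rectified band-passed
#' signal over the burst divided by the burst duration; normalized
#' amplitude is expressed as a percentage of the control-cycle mean.
#'
#' @param time Sample times (s).
#' @param rectified Full-wave rectified band-passed signal.
#' @param onset,offset Burst bounds (s).
#' @param control_mean Mean amplitude of the control-cycle burst, or `NULL`
#'   to skip normalization.
#' @return One-row tibble: `onset`, `offset`, `duration`,
#'   `mean_amplitude`, `normalized_amplitude`.
#' @export
burst_metrics <- function(time, rectified, onset, offset,
                          control_mean = NULL) {
  sel <- time >= onset & time <= offset
  m <- mean(rectified[sel])
  norm <- NA_real_
  if (!is.null(control_mean)) {
    if (!is.finite(control_mean) || control_mean <= 0)
      abort("control-cycle mean amplitude must be positive.",
            class = "quadgait_normalization_error")
    norm <- 100 * m / control_mean
  }
  tibble(onset = onset, offset = offset, duration = offset - onset,
         mean_amplitude = m, normalized_amplitude = norm)
}

#' EMG burst metrics for all valid triads
#'
#' Filters each channel (30--1000 Hz), computes its envelope, detects one
#' burst per limb cycle, and reports burst duration, mean rectified
#' amplitude and amplitude normalized to the control cycle of the same
#' triad (control = 100% by construction).
#'
#' @param triads A `cycle_triads` tibble.
#' @param cycles The cycle tibble the triads refer to.
#' @param emg An `emg_recording` tibble.
#' @param params A [burst_params()].
#' @return Tidy tibble with the same schema as [triad_metrics()]:
#'   variables `emg_burst_duration`, `emg_mean_amplitude`,
#'   `emg_normalized_amplitude`.
#' @export
emg_triad_metrics <- function(triads, cycles, emg,
                              params = burst_params()) {
  rate <- attr(emg, "rate") %||% (1 / median(diff(sort(unique(emg$time)))))
  stim_side <- attr(emg, "stim_side") %||% "right"
  roles <- limb_roles(stim_side)
  tri <- triads |> filter(.data$valid)
  if (nrow(tri) == 0 || nrow(emg) == 0) return(empty_metrics())
  chans <- emg |> distinct(.data$side, .data$muscle)
  res <- list()
  for (ic in seq_len(nrow(chans))) {
    side <- chans$side[ic]; mus <- chans$muscle[ic]
    girdle <- if (mus %in% FORE_MUSCLES) "fore" else "hind"
    lb <- roles$role[roles$side == side & roles$girdle == girdle]
    ch <- emg |> filter(.data$side == !!side, .data$muscle == !!mus) |>
      arrange(.data$time)
    filt <- bandpass_emg(ch$value, rate)
    rect <- abs(filt)
    env <- emg_envelope(filt, rate, params$envelope_hz)
    # windows: the limb's control/stim/post cycles of every valid triad
    win <- list()
    for (sid in unique(tri$stim_id)) {
      row <- tri |> filter(.data$stim_id == sid, .data$limb == lb)
      if (nrow(row) != 1) next
      for (cr in CYCLE_ROLES) {
        cy <- cycles |> filter(.data$limb == lb,
                               .data$cycle == row[[paste0(cr, "_cycle")]])
        if (nrow(cy) == 1)
          win[[length(win) + 1L]] <- tibble(
            stim_id = sid, phase = row$phase, cycle_role = cr,
            start = cy$stance_onset, end = cy$next_onset)
      }
    }
    if (!length(win)) next
    win <- bind_rows(win)
    det <- detect_bursts(env, ch$time, win, params)
    win <- bind_rows(lapply(seq_len(nrow(win)), function(i) {
      if (is.na(det$onset[i]))
        return(mutate(win[i, ], duration = NA_real_,
                      mean_amplitude = NA_real_))
      bm <- burst_metrics(ch$time, rect, det$onset[i], det$offset[i])
      mutate(win[i, ], duration = bm$duration,
             mean_amplitude = bm$mean_amplitude)
    }))
    ctl <- win |> filter(.data$cycle_role == "control") |>
      select("stim_id", control_mean = "mean_amplitude")
    win <- win |> left_join(ctl, by = "stim_id") |>
      mutate(normalized_amplitude = if_else(
        !is.na(.data$control_mean) & .data$control_mean > 0,
        100 * .data$mean_amplitude / .data$control_mean, NA_real_))
    res[[length(res) + 1L]] <- win |>
      mutate(limb = lb, muscle = mus) |>
      select("stim_id", "phase", "cycle_role", "limb", "muscle",
             "duration", "mean_amplitude", "normalized_amplitude") |>
      pivot_longer(c("duration", "mean_amplitude",
                     "normalized_amplitude"),
                   names_to = "variable", values_to = "value") |>
      mutate(variable = paste0("emg_", dplyr::recode(.data$variable,
        duration = "burst_duration",
        mean_amplitude = "mean_amplitude",
        normalized_amplitude = "normalized_amplitude")))
  }
  if (!length(res)) return(empty_metrics())
  bind_rows(res) |>
    select("stim_id", "phase", "cycle_role", "limb", "muscle",
           "variable", "value")
}
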