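#' Step length at the leading limb's stance onset
#'
#' Horizontal distance between the leading and trailing (homologous) toes
#' at the frame of the leading limb's stance onset; reported as a
#' magnitude.
#'
#' @param time Frame times (s) common to both series.
#' @param x_lead,x_trail Toe x series of the leading and trailing limbs.
#' @param onset Stance onset time of the leading limb (s).
#' @return Step length (m).
#' @export
step_length <- function(time, x_lead, x_trail, onset) {
  if (onset < min(time) || onset > max(time))
    abort("onset lies outside the trajectory.",
          class = "quadgait_input_error")
  i <- which.min(abs(time - onset))
  abs(x_lead[i] - x_trail[i])
}

#' Stride length of one cycle on a treadmill
#'
#' Horizontal distance between stance onset and offset plus the distance
#' traveled by the belt during swing (swing duration times belt speed).
#'
#' @param cycle One-row cycle tibble.
#' @param time,x Toe trajectory.
#' @param belt_speed Belt speed (m/s).
#' @return Stride length (m).
#' @export
stride_length <- function(cycle, time, x, belt_speed) {
  i_on <- which.min(abs(time - cycle$stance_onset))
  i_off <- which.min(abs(time - cycle$stance_offset))
  abs(x[i_on] - x[i_off]) + cycle$swing_duration * belt_speed
}

#' Included joint angle from three marker series
#'
#' Angle at the vertex marker between the proximal and distal markers, in
#' degrees within `[0, 180]`; flexion decreases the angle. Frames where
#' the vertex coincides with a neighbour are returned as `NA`.
#'
#' @param px,py,vx,vy,dx,dy Proximal, vertex and distal marker
#'   coordinates (vectors).
#' @return Angle series in degrees.
#' @export
joint_angle <- function(px, py, vx, vy, dx, dy) {
  ax <- px - vx; ay <- py - vy
  bx <- dx - vx; by <- dy - vy
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  cosv <- (ax * bx + ay * by) / (na * nb)
  out <- acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
  out[na == 0 | nb == 0] <- NA_real_
  out
}

#' Summarize a joint-angle series over one cycle
#'
#' @param time Frame times (s).
#' @param angle Angle series (deg).
#' @param cycle One-row cycle tibble.
#' @param max_missing Maximum tolerated fraction of missing frames.
#' @return A one-row tibble: `at_contact`, `at_liftoff`, `max`, `min`,
#'   `excursion` (deg) and `valid`.
#' @export
angle_summary <- function(time, angle, cycle, max_missing = 0.1) {
  sel <- time >= cycle$stance_onset & time < cycle$next_onset
  a <- angle[sel]
  miss <- mean(is.na(a))
  i_on <- which.min(abs(time - cycle$stance_onset))
  i_off <- which.min(abs(time - cycle$stance_offset))
  mx <- suppressWarnings(max(a, na.rm = TRUE))
  mn <- suppressWarnings(min(a, na.rm = TRUE))
  tibble(at_contact = angle[i_on], at_liftoff = angle[i_off],
         max = mx, min = mn, excursion = mx - mn,
         valid = miss <= max_missing && is.finite(mx))
}

#' Maximum marker height over a cycle window
#'
#' Height above the belt surface, optionally low-pass filtered before the
#' maximum is taken (zero-phase Butterworth), which suppresses the upward
#' bias that per-frame tracking jitter adds to a maximum.
#'
#' @param time Frame times (s).
#' @param y Marker height series (m).
#' @param window_start,window_end Cycle window (s).
#' @param rate Sampling rate (Hz), needed when filtering.
#' @param smooth_hz Low-pass cutoff (Hz); `NULL` uses the raw series.
#' @return Maximum height (m).
#' @export
max_marker_height <- function(time, y, window_start, window_end,
                              rate = NULL, smooth_hz = NULL) {
  if (!is.null(smooth_hz)) {
    rate <- rate %||% (1 / median(diff(time)))
    y <- lowpass_series(y, rate, smooth_hz)
  }
  sel <- time >= window_start & time < window_end
  if (!any(sel))
    abort("empty cycle window.", class = "quadgait_input_error")
  max(y[sel], na.rm = TRUE)
}

homologous_limb <- c(ipsi_hind = "contra_hind", contra_hind = "ipsi_hind",
                     homo_fore = "diag_fore", diag_fore = "homo_fore")

#' Spatiotemporal metrics for all valid triads
#'
#' Computes, for every valid triad and every cycle role (control,
#' stimulated, post): per-limb cycle/stance/swing durations, stride and
#' step lengths, maximum marker heights, hindlimb joint-angle excursions,
#' and the support-period category durations of the ipsilateral cycle
#' window.
#'
#' @param triads A `cycle_triads` tibble ([extract_triads()]).
#' @param cycles The cycle tibble the triads refer to.
#' @param markers A `marker_trajectories` tibble.
#' @param belt_speed Belt speed (m/s); defaults to the markers' attribute.
#' @param height_smooth_hz Low-pass cutoff (Hz) for height extraction
#'   (`NULL` for raw maxima, appropriate for noiseless data).
#' @return A tidy tibble: `stim_id`, `phase`, `cycle_role`, `limb`,
#'   `muscle` (`NA` for kinematic variables), `variable`, `value`.
#' @export
triad_metrics <- function(triads, cycles, markers, belt_speed = NULL,
                          height_smooth_hz = 12) {
  v <- belt_speed %||% attr(markers, "belt_speed")
  fr <- attr(markers, "frame_rate") %||%
    (1 / median(diff(sort(unique(markers$time)))))
  stim_side <- attr(markers, "stim_side") %||% "right"
  roles <- limb_roles(stim_side)
  tri <- triads |> filter(.data$valid)
  if (nrow(tri) == 0) return(empty_metrics())

  get_series <- function(side, landmark) {
    markers |>
      filter(.data$side == !!side, .data$landmark == !!landmark) |>
      arrange(.data$time)
  }
  prep <- lapply(seq_len(nrow(roles)), function(i) {
    side <- roles$side[i]; girdle <- roles$girdle[i]
    toe <- get_series(side, if (girdle == "hind") "hind_toe" else "fore_toe")
    sm <- function(y) if (is.null(height_smooth_hz)) y else
      lowpass_series(y, fr, height_smooth_hz)
    out <- list(time = toe$time, toe_x = toe$x, toe_y = toe$y,
                toe_y_s = sm(toe$y))
    if (girdle == "hind") {
      il <- get_series(side, "iliac_crest"); tr <- get_series(side, "trochanter")
      kn <- get_series(side, "knee"); ml <- get_series(side, "malleolus")
      mt <- get_series(side, "mtp")
      out$hip_y_s <- sm(tr$y); out$knee_y_s <- sm(kn$y)
      out$hip_angle <- joint_angle(il$x, il$y, tr$x, tr$y, kn$x, kn$y)
      out$knee_angle <- joint_angle(tr$x, tr$y, kn$x, kn$y, ml$x, ml$y)
      out$ankle_angle <- joint_angle(kn$x, kn$y, ml$x, ml$y, mt$x, mt$y)
    } else {
      hu <- get_series(side, "humerus"); el <- get_series(side, "elbow")
      out$shoulder_y_s <- sm(hu$y); out$elbow_y_s <- sm(el$y)
    }
    out
  })
  names(prep) <- roles$role

  stance_iv <- cycles |>
    select(limb = "limb", onset = "stance_onset", offset = "stance_offset")

  res <- list()
  add <- function(sid, phase, role_cy, lb, variable, value)
    res[[length(res) + 1L]] <<- tibble(
      stim_id = sid, phase = phase, cycle_role = role_cy, limb = lb,
      muscle = NA_character_, variable = variable, value = value)

  for (sid in unique(tri$stim_id)) {
    rows <- tri |> filter(.data$stim_id == sid)
    phase <- rows$phase[1]
    for (r in seq_len(nrow(rows))) {
      lb <- rows$limb[r]
      pr <- prep[[lb]]
      girdle <- roles$girdle[roles$role == lb]
      for (cr in CYCLE_ROLES) {
        cyc_idx <- rows[[paste0(if (cr == "stim") "stim" else cr,
                                "_cycle")]][r]
        cy <- cycles |> filter(.data$limb == lb, .data$cycle == cyc_idx)
        if (nrow(cy) != 1) next
        add(sid, phase, cr, lb, "cycle_duration", cy$cycle_duration)
        add(sid, phase, cr, lb, "stance_duration", cy$stance_duration)
        add(sid, phase, cr, lb, "swing_duration", cy$swing_duration)
        add(sid, phase, cr, lb, "stride_length",
            stride_length(cy, pr$time, pr$toe_x, v))
        trail <- prep[[homologous_limb[[lb]]]]
        add(sid, phase, cr, lb, "step_length",
            step_length(pr$time, pr$toe_x, trail$toe_x, cy$stance_onset))
        add(sid, phase, cr, lb, "toe_height",
            max_marker_height(pr$time, pr$toe_y_s, cy$stance_onset,
                              cy$next_onset))
        if (girdle == "hind") {
          add(sid, phase, cr, lb, "hip_height",
              max_marker_height(pr$time, pr$hip_y_s, cy$stance_onset,
                                cy$next_onset))
          add(sid, phase, cr, lb, "knee_height",
              max_marker_height(pr$time, pr$knee_y_s, cy$stance_onset,
                                cy$next_onset))
          for (j in c("hip", "knee", "ankle")) {
            asum <- angle_summary(pr$time, pr[[paste0(j, "_angle")]], cy)
            if (asum$valid)
              add(sid, phase, cr, lb, paste0(j, "_excursion"),
                  asum$excursion)
          }
        } else {
          add(sid, phase, cr, lb, "shoulder_height",
              max_marker_height(pr$time, pr$shoulder_y_s, cy$stance_onset,
                                cy$next_onset))
          add(sid, phase, cr, lb, "elbow_height",
              max_marker_height(pr$time, pr$elbow_y_s, cy$stance_onset,
                                cy$next_onset))
        }
      }
    }
    # support periods over the ipsilateral cycle window of each role
    irow <- rows |> filter(.data$limb == "ipsi_hind")
    if (nrow(irow) == 1) {
      for (cr in CYCLE_ROLES) {
        cyc_idx <- irow[[paste0(if (cr == "stim") "stim" else cr,
                                "_cycle")]][1]
        cy <- cycles |> filter(.data$limb == "ipsi_hind",
                               .data$cycle == cyc_idx)
        if (nrow(cy) != 1) next
        sup <- support_category_durations(stance_iv, cy$stance_onset,
                                          cy$next_onset)
        for (j in seq_len(nrow(sup)))
          add(sid, phase, cr, NA_character_,
              paste0("support_", sup$category[j]), sup$duration[j])
      }
    }
  }
  bind_rows(res)
}

empty_metrics <- function() {
  tibble(stim_id = integer(), phase = character(), cycle_role = character(),
         limb = character(), muscle = character(), variable = character(),
         value = numeric())
}
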