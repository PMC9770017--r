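#' Read and write marker trajectories (tracking CSV dialect)
#'
#' The on-disk format follows the common motion-tracking CSV layout with
#' three header rows (`scorer`, `bodyparts`, `coords`) and one row per
#' video frame; body parts are named `<side>_<landmark>` and coordinates
#' are calibrated meters in the treadmill frame (x along the direction of
#' travel, y above the belt surface). Values are written with full
#' precision, so a write-read round trip is bit-exact.
#'
#' @param path File path.
#' @param frame_rate Video frame rate (Hz) used to reconstruct time.
#' @param belt_speed,stim_side,animal_id Metadata attached to the result.
#' @param require_all If `TRUE`, all 12 landmarks per side must be
#'   present; unknown body parts are kept and reported via a message.
#' @return A `marker_trajectories` tibble.
#' @export
read_marker_csv <- function(path, frame_rate = 60, belt_speed = NA_real_,
                            stim_side = "right", animal_id = NA,
                            require_all = TRUE) {
  if (!file.exists(path))
    abort(paste0("marker file not found: ", path),
          class = "quadgait_io_error")
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L || !startsWith(hdr[2], "bodyparts") ||
      !startsWith(hdr[3], "coords"))
    abort("expected a 3-row header (scorer/bodyparts/coords).",
          class = "quadgait_format_error")
  parts <- strsplit(hdr[2], ",", fixed = TRUE)[[1]][-1]
  coords <- strsplit(hdr[3], ",", fixed = TRUE)[[1]][-1]
  dat <- utils::read.csv(path, skip = 3L, header = FALSE,
                         colClasses = "numeric")
  if (ncol(dat) != length(parts) + 1L)
    abort("header and data column counts disagree.",
          class = "quadgait_format_error")
  frames <- as.integer(dat[[1]])
  if (length(frames) > 1 && any(diff(frames) != 1L))
    abort("non-uniform frame index (sampling error).",
          class = "quadgait_sampling_error")
  required <- as.vector(outer(c("left", "right"), ALL_LANDMARKS, paste,
                              sep = "_"))
  missing_lm <- setdiff(required, unique(parts))
  if (require_all && length(missing_lm))
    abort(paste0("missing required landmark(s): ",
                 paste(missing_lm, collapse = ", ")),
          class = "quadgait_format_error")
  unknown <- setdiff(unique(parts), required)
  if (length(unknown))
    inform(paste0("unknown body parts kept: ",
                  paste(unknown, collapse = ", ")))
  cols <- lapply(unique(parts), function(bp) {
    ix <- which(parts == bp & coords == "x") + 1L
    iy <- which(parts == bp & coords == "y") + 1L
    if (length(ix) != 1 || length(iy) != 1)
      abort(paste0("body part lacks x/y pair: ", bp),
            class = "quadgait_format_error")
    side <- sub("_(.*)$", "", bp)
    tibble(time = frames / frame_rate, frame = frames, side = side,
           landmark = sub("^(left|right)_", "", bp),
           x = dat[[ix]], y = dat[[iy]])
  })
  mk <- bind_rows(cols)
  if (any(!is.finite(mk$x)) || any(!is.finite(mk$y)))
    abort("marker coordinates contain non-finite values.",
          class = "quadgait_format_error")
  new_markers(mk, frame_rate = frame_rate, belt_speed = belt_speed,
              animal_id = animal_id, stim_side = stim_side)
}

#' @rdname read_marker_csv
#' @param markers A `marker_trajectories` tibble.
#' @param scorer Scorer label written in the first header row.
#' @export
write_marker_csv <- function(markers, path, scorer = "quadgait") {
  wide <- markers |>
    mutate(bodypart = paste(.data$side, .data$landmark, sep = "_")) |>
    arrange(.data$frame)
  bps <- unique(wide$bodypart)
  frames <- sort(unique(wide$frame))
  mat <- matrix(NA_real_, nrow = length(frames), ncol = 2 * length(bps))
  for (i in seq_along(bps)) {
    sub <- wide[wide$bodypart == bps[i], ]
    ord <- match(sub$frame, frames)
    mat[ord, 2 * i - 1L] <- sub$x
    mat[ord, 2 * i] <- sub$y
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste(c("scorer", rep(scorer, 2 * length(bps))), collapse = ","),
    paste(c("bodyparts", rep(bps, each = 2)), collapse = ","),
    paste(c("coords", rep(c("x", "y"), length(bps))), collapse = ",")),
    con)
  body <- apply(cbind(frames, mat), 1L, function(r)
    paste(c(sprintf("%d", as.integer(r[1])),
            sprintf("%.17g", r[-1])), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read and write EMG recordings (wide CSV)
#'
#' Columns: `time` (s) plus one `<side>_<muscle>` column per channel.
#'
#' @param path File path.
#' @param stim_side,animal_id Metadata attached to the result.
#' @return An `emg_recording` tibble.
#' @export
read_emg_csv <- function(path, stim_side = "right", animal_id = NA) {
  if (!file.exists(path))
    abort(paste0("EMG file not found: ", path),
          class = "quadgait_io_error")
  dat <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!"time" %in% names(dat))
    abort("EMG file lacks a `time` column.",
          class = "quadgait_format_error")
  dt <- diff(dat$time)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9)
    abort("non-uniform EMG sampling.", class = "quadgait_sampling_error")
  chans <- setdiff(names(dat), "time")
  ok <- grepl("^(left|right)_", chans)
  mus <- sub("^(left|right)_", "", chans)
  if (any(!ok) || !all(mus %in% ALL_MUSCLES))
    abort(paste0("unknown EMG channel(s): ",
                 paste(chans[!ok | !(mus %in% ALL_MUSCLES)],
                       collapse = ", ")),
          class = "quadgait_format_error")
  out <- dat |>
    pivot_longer(-"time", names_to = "channel", values_to = "value") |>
    mutate(side = sub("_(.*)$", "", .data$channel),
           muscle = sub("^(left|right)_", "", .data$channel)) |>
    select("time", "side", "muscle", "value")
  structure(out, class = c("emg_recording", class(tibble())),
            rate = if (length(dt)) 1 / median(dt) else NA_real_,
            animal_id = animal_id, stim_side = stim_side)
}

#' @rdname read_emg_csv
#' @param emg An `emg_recording` tibble.
#' @export
write_emg_csv <- function(emg, path) {
  wide <- emg |>
    mutate(channel = paste(.data$side, .data$muscle, sep = "_")) |>
    select("time", "channel", "value") |>
    pivot_wider(names_from = "channel", values_from = "value")
  # full-precision text so a write -> read round trip is bit-exact
  txt <- vapply(wide, function(col) sprintf("%.17g", col),
                character(nrow(wide)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(wide), collapse = ","), con)
  writeLines(apply(txt, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read and write stimulus events (TSV)
#'
#' Columns: `onset_s`, `side`, optionally `stim_id` and `phase_target`.
#' An empty file yields an empty stimulus table and the pipeline proceeds
#' with zero triads.
#'
#' @param path File path.
#' @return Tibble with columns `stim_id`, `onset`, `side` (and
#'   `phase_target` if present).
#' @export
read_stimuli <- function(path) {
  if (!file.exists(path))
    abort(paste0("stimulus file not found: ", path),
          class = "quadgait_io_error")
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(dat) == 0)
    return(tibble(stim_id = integer(), onset = numeric(),
                  side = character()))
  if (!all(c("onset_s", "side") %in% names(dat)))
    abort("stimulus file needs columns `onset_s` and `side`.",
          class = "quadgait_format_error")
  if (any(!is.finite(dat$onset_s)))
    abort("stimulus onsets must be finite.",
          class = "quadgait_format_error")
  out <- dat |> rename(onset = "onset_s")
  if (!"stim_id" %in% names(out))
    out$stim_id <- seq_len(nrow(out))
  out |> select("stim_id", "onset", "side", dplyr::any_of("phase_target"))
}

#' @rdname read_stimuli
#' @param stimuli Stimulus tibble (`stim_id`, `onset`, `side`, ...).
#' @export
write_stimuli <- function(stimuli, path) {
  out <- stimuli |> rename(onset_s = "onset")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
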