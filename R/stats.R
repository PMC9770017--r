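#' Convert a footfall schedule to gait cycles
#'
#' Reads cycles directly off the schedule's event times (the schedule-level
#' equivalent of marker-based detection), with the same columns as
#' [build_cycles()].
#'
#' @param schedule A `footfall_schedule`.
#' @return Cycle tibble for the four limb roles.
#' @export
schedule_cycles <- function(schedule) {
  as_tibble(schedule) |>
    mutate(cycle_duration = .data$next_onset - .data$stance_onset,
           stance_duration = .data$stance_offset - .data$stance_onset,
           swing_duration = .data$cycle_duration - .data$stance_duration) |>
    select("limb", "cycle", "stance_onset", "stance_offset", "next_onset",
           "cycle_duration", "stance_duration", "swing_duration")
}

#' Duration and support metrics without marker data
#'
#' Schedule-level counterpart of [triad_metrics()]: per-limb durations and
#' (optionally) support-period category durations, for analyses that start
#' from event times rather than marker trajectories.
#'
#' @inheritParams triad_metrics
#' @param support Include support-period decomposition.
#' @return Tidy metrics tibble (same schema as [triad_metrics()]).
#' @export
triad_duration_metrics <- function(triads, cycles, support = TRUE) {
  tri <- triads |> filter(.data$valid)
  if (nrow(tri) == 0) return(empty_metrics())
  stance_iv <- cycles |>
    select(limb = "limb", onset = "stance_onset", offset = "stance_offset")
  res <- list()
  for (i in seq_len(nrow(tri))) {
    row <- tri[i, ]
    for (cr in CYCLE_ROLES) {
      cy <- cycles |> filter(.data$limb == row$limb,
                             .data$cycle == row[[paste0(cr, "_cycle")]])
      if (nrow(cy) != 1) next
      res[[length(res) + 1L]] <- tibble(
        stim_id = row$stim_id, phase = row$phase, cycle_role = cr,
        limb = row$limb, muscle = NA_character_,
        variable = c("cycle_duration", "stance_duration",
                     "swing_duration"),
        value = c(cy$cycle_duration, cy$stance_duration,
                  cy$swing_duration))
      if (support && row$limb == "ipsi_hind") {
        sup <- support_category_durations(stance_iv, cy$stance_onset,
                                          cy$next_onset)
        res[[length(res) + 1L]] <- tibble(
          stim_id = row$stim_id, phase = row$phase, cycle_role = cr,
          limb = NA_character_, muscle = NA_character_,
          variable = paste0("support_", sup$category),
          value = sup$duration)
      }
    }
  }
  bind_rows(res)
}

#' Aggregate triad metrics into per-animal means
#'
#' For each phase and variable, averages each animal's valid triads per
#' cycle role. Animals lacking a complete control/stim/post set for a
#' variable are dropped from that variable's block.
#'
#' @param metrics Tidy metrics tibble with an `animal` column.
#' @return Tibble with columns `phase`, `limb`, `muscle`, `variable`,
#'   `animal`, `control`, `stim`, `post`.
#' @export
aggregate_phase <- function(metrics) {
  empty <- tibble(phase = character(), limb = character(),
                  muscle = character(), variable = character(),
                  animal = integer(), control = numeric(),
                  stim = numeric(), post = numeric())
  if (nrow(metrics) == 0) return(empty)
  out <- metrics |>
    filter(!is.na(.data$value)) |>
    group_by(.data$phase, .data$limb, .data$muscle, .data$variable,
             .data$animal, .data$cycle_role) |>
    summarise(value = mean(.data$value), .groups = "drop")
  if (nrow(out) == 0) return(empty)
  out <- pivot_wider(out, names_from = "cycle_role",
                     values_from = "value")
  for (cr in CYCLE_ROLES) if (!cr %in% names(out)) out[[cr]] <- NA_real_
  out |>
    filter(!is.na(.data$control), !is.na(.data$stim), !is.na(.data$post))
}

#' Friedman repeated-measures rank test across the three cycles
#'
#' @param mat Numeric matrix, animals x 3 (control, stimulated, post).
#' @return One-row tibble: `statistic` (chi-square with tie correction),
#'   `df`, `p_value`.
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) != 3)
    abort("need >= 2 animals and exactly 3 cycle columns.",
          class = "quadgait_stats_error")
  if (all(mat == mat[, 1]))  # total ties: no evidence against the null
    return(tibble(statistic = 0, df = 2, p_value = 1))
  ft <- friedman.test(mat)
  tibble(statistic = unname(ft$statistic),
         df = unname(ft$parameter), p_value = ft$p.value)
}

#' Bonferroni-adjusted post hoc comparisons against control
#'
#' Pairwise Wilcoxon signed-rank tests (stimulated vs control, post vs
#' control); raw p values are multiplied by the number of reported
#' comparisons and capped at 1.
#'
#' @param mat Numeric matrix, animals x 3 (control, stimulated, post).
#' @param comparisons Number of comparisons entering the correction.
#' @return One-row tibble: `p_stim_vs_control`, `p_post_vs_control`.
#' @export
bonferroni_posthoc <- function(mat, comparisons = 2) {
  mat <- as.matrix(mat)
  pw <- function(a, b) {
    if (all(a == b)) return(1)
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                       exact = TRUE))
    min(1, wt$p.value * comparisons)
  }
  tibble(p_stim_vs_control = pw(mat[, 2], mat[, 1]),
         p_post_vs_control = pw(mat[, 3], mat[, 1]))
}

#' Per-animal percent change versus control
#'
#' 100 * (value - control) / control per animal, summarized as group mean
#' and SD for the stimulated and post cycles.
#'
#' @param mat Numeric matrix, animals x 3 (control, stimulated, post).
#' @return One-row tibble: `pct_stim`, `pct_stim_sd`, `pct_post`,
#'   `pct_post_sd` (all `NA` when any control value is non-positive).
#' @export
percent_change <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat[, 1] <= 0))
    return(tibble(pct_stim = NA_real_, pct_stim_sd = NA_real_,
                  pct_post = NA_real_, pct_post_sd = NA_real_))
  ps <- 100 * (mat[, 2] - mat[, 1]) / mat[, 1]
  pp <- 100 * (mat[, 3] - mat[, 1]) / mat[, 1]
  tibble(pct_stim = mean(ps), pct_stim_sd = sd(ps),
         pct_post = mean(pp), pct_post_sd = sd(pp))
}

#' Per-phase effect tables with Friedman and post hoc statistics
#'
#' For every phase and variable: per-cycle group mean and SD, per-animal
#' percent changes versus control, Shapiro-Wilk normality per cycle
#' (reported, but never gating the nonparametric test), the Friedman test
#' across the three cycles, and Bonferroni-adjusted Wilcoxon post hoc
#' comparisons against control.
#'
#' @param metrics Tidy metrics tibble with an `animal` column (see
#'   [analyze_study()]).
#' @param min_animals Minimum animals required to run the statistics.
#' @return A tibble of class `gait_stats`, one row per phase x variable
#'   (x limb x muscle).
#' @export
gait_phase_stats <- function(metrics, min_animals = 2) {
  agg <- aggregate_phase(metrics)
  groups <- agg |>
    distinct(.data$phase, .data$limb, .data$muscle, .data$variable)
  res <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- agg |>
      filter(.data$phase == g$phase,
             (.data$limb == g$limb | (is.na(.data$limb) & is.na(g$limb))),
             (.data$muscle == g$muscle |
                (is.na(.data$muscle) & is.na(g$muscle))),
             .data$variable == g$variable)
    mat <- as.matrix(sub[, c("control", "stim", "post")])
    base <- tibble(phase = g$phase, limb = g$limb, muscle = g$muscle,
                   variable = g$variable, n_animals = nrow(sub),
                   mean_control = mean(mat[, 1]), sd_control = sd(mat[, 1]),
                   mean_stim = mean(mat[, 2]), sd_stim = sd(mat[, 2]),
                   mean_post = mean(mat[, 3]), sd_post = sd(mat[, 3]))
    sw <- function(v) {
      if (length(v) < 3 || length(unique(v)) == 1) return(NA_real_)
      shapiro.test(v)$p.value
    }
    base <- base |> mutate(shapiro_p_control = sw(mat[, 1]),
                           shapiro_p_stim = sw(mat[, 2]),
                           shapiro_p_post = sw(mat[, 3]))
    if (nrow(sub) < min_animals) {
      base |> mutate(friedman_chisq = NA_real_, friedman_df = NA_real_,
                     friedman_p = NA_real_,
                     p_stim_vs_control = NA_real_,
                     p_post_vs_control = NA_real_,
                     pct_stim = NA_real_, pct_stim_sd = NA_real_,
                     pct_post = NA_real_, pct_post_sd = NA_real_)
    } else {
      ft <- friedman_rank_test(mat)
      ph <- bonferroni_posthoc(mat)
      pc <- percent_change(mat)
      base |> mutate(friedman_chisq = ft$statistic,
                     friedman_df = ft$df, friedman_p = ft$p_value,
                     p_stim_vs_control = ph$p_stim_vs_control,
                     p_post_vs_control = ph$p_post_vs_control) |>
        bind_cols(pc)
    }
  })
  out <- bind_rows(res)
  structure(out, class = c("gait_stats", class(tibble())),
            aggregates = agg)
}

#' Analyze one session end to end
#'
#' Detects cycles from the markers (or reads them off the schedule when no
#' markers are present), extracts triads, and computes spatiotemporal and
#' EMG metrics.
#'
#' @param session A `gait_session` (or a list with `markers`/`schedule`,
#'   `stimuli`, optional `emg`).
#' @param event_params An [event_params()].
#' @param windows A [phase_windows()].
#' @param height_smooth_hz Low-pass cutoff for height extraction.
#' @param emg_params A [burst_params()].
#' @return A list of class `gait_analysis`: `cycles`, `triads`, `metrics`.
#' @export
analyze_session <- function(session, event_params = quadgait::event_params(),
                            windows = phase_windows(),
                            height_smooth_hz = 12,
                            emg_params = burst_params()) {
  if (!is.null(session$markers)) {
    cycles <- detect_cycles(session$markers, params = event_params)
  } else {
    cycles <- schedule_cycles(session$schedule)
  }
  triads <- extract_triads(session$stimuli, cycles, windows)
  metrics <- if (!is.null(session$markers)) {
    triad_metrics(triads, cycles, session$markers,
                  height_smooth_hz = height_smooth_hz)
  } else {
    triad_duration_metrics(triads, cycles)
  }
  if (!is.null(session$emg) && nrow(session$emg) > 0)
    metrics <- bind_rows(metrics,
                         emg_triad_metrics(triads, cycles, session$emg,
                                           emg_params))
  structure(list(cycles = cycles, triads = triads, metrics = metrics),
            class = "gait_analysis")
}

#' Analyze a multi-animal study and compute phase statistics
#'
#' @param study A `gait_study` ([simulate_study()]) or list of sessions.
#' @param ... Passed to [analyze_session()].
#' @return A list of class `gait_study_analysis`: `metrics` (with `animal`
#'   column), `stats` (a `gait_stats` table) and `analyses`.
#' @export
analyze_study <- function(study, ...) {
  analyses <- lapply(study, analyze_session, ...)
  metrics <- bind_rows(lapply(seq_along(study), function(i)
    analyses[[i]]$metrics |>
      mutate(animal = study[[i]]$animal$animal_id)))
  structure(list(metrics = metrics,
                 stats = gait_phase_stats(metrics),
                 analyses = analyses),
            class = "gait_study_analysis")
}

#' Ground-truth effects of a simulated study
#'
#' @param study A `gait_study`.
#' @return Tibble of injected multipliers with an `animal` column.
#' @export
study_truth <- function(study) {
  bind_rows(lapply(study, function(s)
    s$truth |> mutate(animal = s$animal$animal_id)))
}

#' Type-I error calibration of the Friedman test on null sessions
#'
#' Simulates effect-free sessions (footfall schedules with timing jitter
#' and inter-animal variability, no perturbation), measures the
#' ipsilateral swing duration of the control/stimulated/post cycles around
#' sham stimuli, aggregates per animal and applies the Friedman test --
#' returning one p value per replicate.
#'
#' @param n_replicates Number of null sessions.
#' @param n_animals Animals per session.
#' @param n_triads Sham stimuli per animal.
#' @param spacing Integer range of cycles between stimuli.
#' @param config A [session_config()] supplying noise scales.
#' @return Numeric vector of Friedman p values (length `n_replicates`).
#' @export
friedman_null_pvalues <- function(n_replicates = 2000, n_animals = 7,
                                  n_triads = 10, spacing = c(5L, 6L),
                                  config = session_config()) {
  n_cycles <- 2L + n_triads * spacing[2] + 2L
  vapply(seq_len(n_replicates), function(r) {
    vals <- vapply(seq_len(n_animals), function(a) {
      an <- animal_params(config, a)
      sched <- build_footfall_schedule(an, n_cycles)
      sub <- sched[sched$limb == "ipsi_hind", ]
      sub <- sub[order(sub$cycle), ]
      swing <- sub$next_onset - sub$stance_offset
      steps <- if (spacing[1] == spacing[2]) rep(spacing[1], n_triads) else
        sample(seq(spacing[1], spacing[2]), n_triads, replace = TRUE)
      ks <- 1L + cumsum(steps)
      idx <- match(ks, sub$cycle)
      c(mean(swing[idx - 1L]), mean(swing[idx]), mean(swing[idx + 1L]))
    }, numeric(3))
    friedman_rank_test(t(vals))$p_value
  }, numeric(1))
}
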