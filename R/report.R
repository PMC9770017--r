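#' Write per-phase effect tables and a JSON summary
#'
#' Emits one `effects_<phase>.tsv` per phase plus `stats.json` containing
#' the full table; an empty analysis yields empty but schema-valid files.
#'
#' @param stats A `gait_stats` table ([gait_phase_stats()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
build_report <- function(stats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  phases <- if (nrow(stats)) unique(stats$phase) else character()
  for (p in phases) {
    f <- file.path(dir, paste0("effects_", p, ".tsv"))
    readr::write_tsv(stats |> filter(.data$phase == p), f,
                     progress = FALSE)
    paths <- c(paths, f)
  }
  jf <- file.path(dir, "stats.json")
  jsonlite::write_json(as.data.frame(stats), jf, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(paths, jf))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a phase-effect table
#'
#' One row per phase x variable x cycle role with the group mean, SD and,
#' for stimulated/post cycles, the percent change versus control and the
#' Bonferroni-adjusted post hoc p value.
#'
#' @param x A `gait_stats` table.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gait_stats <- function(x, ...) {
  base <- as_tibble(x)
  long <- lapply(CYCLE_ROLES, function(cr) {
    base |>
      mutate(cycle_role = cr,
             mean = .data[[paste0("mean_", cr)]],
             sd = .data[[paste0("sd_", cr)]],
             pct_change = switch(cr, control = 0,
                                 stim = .data$pct_stim,
                                 post = .data$pct_post),
             p_adjusted = switch(cr, control = NA_real_,
                                 stim = .data$p_stim_vs_control,
                                 post = .data$p_post_vs_control)) |>
      select("phase", "limb", "muscle", "variable", "n_animals",
             "cycle_role", "mean", "sd", "pct_change", "p_adjusted",
             "friedman_p")
  })
  bind_rows(long) |> arrange(.data$phase, .data$variable)
}

#' Glance at a phase-effect table
#'
#' @param x A `gait_stats` table.
#' @param alpha Significance level.
#' @param ... Unused.
#' @return One-row tibble with counts of tested and significant effects.
#' @export
glance.gait_stats <- function(x, alpha = 0.05, ...) {
  tibble(n_effects = nrow(x),
         n_friedman_significant = sum(x$friedman_p < alpha, na.rm = TRUE),
         n_stim_significant = sum(x$friedman_p < alpha &
                                    x$p_stim_vs_control < alpha,
                                  na.rm = TRUE),
         n_post_significant = sum(x$friedman_p < alpha &
                                    x$p_post_vs_control < alpha,
                                  na.rm = TRUE))
}
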