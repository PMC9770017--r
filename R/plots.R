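#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_segment
#'   geom_line facet_wrap facet_grid labs theme_minimal autoplot
#'   position_dodge geom_rect scale_y_discrete geom_text vars
NULL

#' Plot group means per cycle for selected variables
#'
#' Mirrors the standard per-phase figure layout: group mean and SD for the
#' control, stimulated and post cycles, one panel per phase, with an
#' asterisk where the Bonferroni-adjusted post hoc comparison against
#' control is significant.
#'
#' @param stats A `gait_stats` table.
#' @param variables Variables to plot (default: all).
#' @param alpha Significance level for the asterisks.
#' @return A ggplot object.
#' @export
plot_phase_effects <- function(stats, variables = NULL, alpha = 0.05) {
  td <- tidy(stats)
  if (!is.null(variables))
    td <- td |> filter(.data$variable %in% variables)
  td <- td |>
    mutate(cycle_role = factor(.data$cycle_role, levels = CYCLE_ROLES),
           panel = ifelse(is.na(.data$limb), .data$variable,
                          paste(.data$variable, .data$limb, sep = "\n")),
           sig = ifelse(!is.na(.data$p_adjusted) &
                          .data$p_adjusted < alpha &
                          .data$friedman_p < alpha, "*", ""))
  ggplot(td, aes(x = .data$cycle_role, y = .data$mean)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.15) +
    geom_point(size = 2) +
    geom_text(aes(label = .data$sig, y = .data$mean + .data$sd),
              vjust = -0.4, size = 5) +
    facet_grid(rows = vars(.data$panel), cols = vars(.data$phase),
               scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot the support-period decomposition of a window
#'
#' @param periods Output of [support_periods()].
#' @return A ggplot object.
#' @export
plot_support_periods <- function(periods) {
  ggplot(periods,
         aes(xmin = .data$start, xmax = .data$end,
             ymin = 0, ymax = 1, fill = .data$category)) +
    geom_rect(colour = "white") +
    labs(x = "time (s)", y = NULL, fill = "support") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.gait_stats <- function(object, ...) plot_phase_effects(object, ...)

#' Plot a footfall schedule as stance bars
#'
#' @param object A `footfall_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.footfall_schedule <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(limb = factor(.data$limb, levels = rev(LIMB_ROLES)))
  ggplot(df, aes(y = .data$limb)) +
    geom_segment(aes(x = .data$stance_onset, xend = .data$stance_offset,
                     yend = .data$limb), linewidth = 4) +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}
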