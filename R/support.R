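#' Support-period decomposition of a cycle window
#'
#' Splits one ipsilateral cycle window into maximal intervals during which
#' the set of limbs in stance is constant. Quadrupedal walking generally
#' shows eight support periods per cycle, alternating triple and double
#' support; a diagonal double support can be replaced by a period of
#' quadrupedal support, giving nine distinct categories in total (four
#' doubles, four triples, quadrupedal).
#'
#' @param stance A tibble of stance intervals with columns `limb` (role),
#'   `onset`, `offset`, covering the window's neighbourhood (see
#'   [schedule_stance_intervals()]).
#' @param window_start,window_end Window bounds in seconds, normally one
#'   ipsilateral cycle `[stance_onset, next_onset)`.
#' @return A tibble with columns `start`, `end`, `duration`, `n_limbs`,
#'   `limbs` (limb roles joined by `+`) and `category` (one of the nine
#'   support categories, or `"other"` for configurations not seen in
#'   steady walking, e.g. fewer than two limbs in stance).
#' @export
#' @examples
#' an <- animal_params(session_config(noise = list(animal_sigma = 0)))
#' sched <- build_footfall_schedule(an, n_cycles = 6, timing_jitter = 0)
#' st <- schedule_stance_intervals(sched)
#' support_periods(st, window_start = 2, window_end = 3)
support_periods <- function(stance, window_start, window_end) {
  stopifnot(window_end > window_start)
  st <- stance |>
    filter(.data$offset > window_start, .data$onset < window_end)
  if (nrow(st) == 0)
    abort("no limb is ever in stance within the window.",
          class = "quadgait_input_error")
  bp <- sort(unique(c(window_start, window_end,
                      pmax(pmin(c(st$onset, st$offset), window_end),
                           window_start))))
  starts <- bp[-length(bp)]
  ends <- bp[-1L]
  keep <- ends - starts > 1e-12
  starts <- starts[keep]; ends <- ends[keep]
  mids <- (starts + ends) / 2
  in_stance <- vapply(mids, function(m) {
    roles <- st$limb[st$onset <= m & m < st$offset]
    paste(LIMB_ROLES[LIMB_ROLES %in% roles], collapse = "+")
  }, character(1))
  # merge consecutive intervals with identical limb sets
  grp <- cumsum(c(TRUE, in_stance[-1L] != in_stance[-length(in_stance)]))
  out <- tibble(start = starts, end = ends, limbs = in_stance, grp = grp) |>
    group_by(.data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              limbs = first(.data$limbs), .groups = "drop") |>
    select(!"grp") |>
    mutate(duration = .data$end - .data$start,
           n_limbs = lengths(strsplit(.data$limbs, "+", fixed = TRUE)),
           category = support_category(.data$limbs)) |>
    select("start", "end", "duration", "n_limbs", "limbs", "category") |>
    arrange(.data$start)
  out
}

#' Label a limb set with its support category
#'
#' @param limbs Character vector of `+`-joined limb roles.
#' @return Character vector of category labels.
#' @export
support_category <- function(limbs) {
  vapply(limbs, function(s) {
    set <- strsplit(s, "+", fixed = TRUE)[[1]]
    has <- LIMB_ROLES %in% set
    names(has) <- LIMB_ROLES
    k <- sum(has)
    if (k == 4) return("quad")
    if (k == 3) {
      missing_limb <- LIMB_ROLES[!has]
      return(paste0("triple_no_", sub("_(hind|fore)$", "", missing_limb)))
    }
    if (k == 2) {
      if (has[["ipsi_hind"]] && has[["homo_fore"]]) return("double_ipsi_homo")
      if (has[["ipsi_hind"]] && has[["diag_fore"]]) return("double_ipsi_diag")
      if (has[["contra_hind"]] && has[["homo_fore"]])
        return("double_contra_homo")
      if (has[["contra_hind"]] && has[["diag_fore"]])
        return("double_contra_diag")
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' Total duration per support category in a window
#'
#' Durations of recurring categories are summed within the window.
#'
#' @inheritParams support_periods
#' @param all_categories If `TRUE`, report all nine categories (zero for
#'   absent ones); otherwise only categories present.
#' @return Tibble with columns `category`, `duration`.
#' @export
support_category_durations <- function(stance, window_start, window_end,
                                       all_categories = TRUE) {
  per <- support_periods(stance, window_start, window_end)
  agg <- per |>
    group_by(.data$category) |>
    summarise(duration = sum(.data$duration), .groups = "drop")
  if (all_categories) {
    base <- tibble(category = SUPPORT_CATEGORIES)
    agg <- base |>
      left_join(agg, by = "category") |>
      mutate(duration = if_else(is.na(.data$duration), 0, .data$duration))
  }
  agg
}
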