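# Independent brute-force Friedman statistic: rank within rows (average
# ranks for ties), chi-square with the standard tie correction.
brute_friedman <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  r <- t(apply(mat, 1, rank))
  Rj <- colSums(r)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(mat, 1, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  stat / corr
}

test_that("Friedman statistic matches the hand rank-sum computation", {
  m <- matrix(c(1:7, (1:7) + 10, (1:7) + 20), ncol = 3)
  ft <- friedman_rank_test(m)
  expect_equal(ft$statistic, 14)
  expect_equal(ft$df, 2)
  # identical columns: no evidence, statistic 0, p = 1
  same <- matrix(rep(1:6, 3), ncol = 3)
  ft0 <- friedman_rank_test(same)
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p_value, 1)
  expect_error(friedman_rank_test(matrix(1:3, 1)),
               class = "quadgait_stats_error")
})

test_that("Friedman agrees with brute-force ranks on random matrices", {
  set.seed(40)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    m <- matrix(sample(1:5, n * 3, replace = TRUE), ncol = 3)
    if (all(m == m[, 1])) next
    ties <- sum(apply(m, 1, function(row) {
      tt <- table(row); sum(tt^3 - tt)
    }))
    if (ties == n * 3 * 8) next  # fully degenerate rows
    expect_equal(friedman_rank_test(m)$statistic, brute_friedman(m),
                 tolerance = 1e-9)
  }
})

test_that("Bonferroni post hoc multiplies and caps the pairwise p values", {
  ctl <- c(1, 2, 3, 4, 5, 6, 7)
  m <- cbind(ctl, ctl * 1.25, ctl)
  ph <- bonferroni_posthoc(m)
  # all 7 signed ranks positive: exact p = 2/128, times 2 comparisons
  expect_equal(ph$p_stim_vs_control, 2 * 2 / 128)
  expect_equal(ph$p_post_vs_control, 1)  # all differences zero
  m2 <- cbind(ctl, ctl + c(1, -1, 1, -1, 1, -1, 0.5), ctl)
  expect_lte(bonferroni_posthoc(m2)$p_stim_vs_control, 1)
})

test_that("percent change versus control follows the direct formula", {
  m <- cbind(rep(0.5, 5), rep(0.6175, 5), rep(0.5, 5))
  pc <- percent_change(m)
  expect_equal(pc$pct_stim, 23.5)
  expect_equal(pc$pct_post, 0)
  same <- cbind(1:4, 1:4, 1:4)
  expect_equal(percent_change(same)$pct_stim, 0)
  bad <- cbind(c(1, 0), c(2, 2), c(1, 1))
  expect_true(is.na(percent_change(bad)$pct_stim))
})

test_that("aggregation averages triads per animal and drops empty animals", {
  met <- tibble::tibble(
    stim_id = rep(1:3, each = 3),
    phase = "mid_swing",
    cycle_role = rep(c("control", "stim", "post"), 3),
    limb = "ipsi_hind", muscle = NA_character_,
    variable = "swing_duration",
    value = c(1, 1, 1, 1, 2, 1, 1, 3, 1),
    animal = 1)
  agg <- aggregate_phase(met)
  expect_equal(agg$stim, 2)
  expect_equal(agg$control, 1)
  # an animal with no valid triads contributes no row
  expect_equal(nrow(dplyr::filter(agg, animal == 2)), 0L)
})

test_that("phase statistics are skipped below two animals", {
  met <- tibble::tibble(
    stim_id = 1, phase = "mid_swing",
    cycle_role = c("control", "stim", "post"),
    limb = "ipsi_hind", muscle = NA_character_,
    variable = "swing_duration", value = c(1, 2, 1), animal = 1)
  st <- gait_phase_stats(met)
  expect_true(is.na(st$friedman_p))
  expect_equal(st$n_animals, 1L)
})

test_that("Shapiro-Wilk flags planted non-normality and respects n >= 3", {
  set.seed(50)
  bimodal <- c(rnorm(30, -4, 0.3), rnorm(30, 4, 0.3))
  expect_lt(shapiro.test(bimodal)$p.value, 0.01)
  met <- tibble::tibble(
    stim_id = 1, phase = "mid_swing",
    cycle_role = rep(c("control", "stim", "post"), 2),
    limb = "ipsi_hind", muscle = NA_character_,
    variable = "swing_duration", value = c(1, 2, 1, 1.1, 2.1, 1.2),
    animal = rep(1:2, each = 3))
  st <- gait_phase_stats(met)
  expect_true(is.na(st$shapiro_p_control))  # n = 2 < 3
})

test_that("planted 25% effects are detected with high power at n = 7", {
  set.seed(60)
  hits <- 0L
  for (i in 1:500) {
    ctl <- exp(rnorm(7, 0, 0.1))
    stim <- ctl * 1.25 * exp(rnorm(7, 0, 0.05))
    post <- ctl * exp(rnorm(7, 0, 0.05))
    ph <- bonferroni_posthoc(cbind(ctl, stim, post))
    hits <- hits + (ph$p_stim_vs_control < 0.05)
  }
  expect_gte(hits / 500, 0.9)
})

test_that("null calibration machinery returns one p value per replicate", {
  cfg <- session_config(seed = 3)
  set.seed(3)
  p <- friedman_null_pvalues(60, n_animals = 5, n_triads = 4, config = cfg)
  expect_length(p, 60)
  expect_true(all(p >= 0 & p <= 1))
  # sanity: not grossly anticonservative on a small run
  expect_lt(mean(p < 0.05), 0.2)
})

test_that("tidy and glance summarize a phase-effect table", {
  met <- tibble::tibble(
    stim_id = rep(1:2, each = 6),
    phase = "mid_swing",
    cycle_role = rep(c("control", "stim", "post"), 4),
    limb = "ipsi_hind", muscle = NA_character_,
    variable = "swing_duration",
    value = rep(c(1, 1.3, 1), 4) * exp(rnorm(12, 0, 0.01)),
    animal = rep(1:2, 2, each = 3))
  st <- gait_phase_stats(met)
  td <- tidy(st)
  expect_setequal(td$cycle_role, CYCLE_ROLES)
  expect_true(all(c("pct_change", "p_adjusted") %in% names(td)))
  gl <- glance(st)
  expect_equal(gl$n_effects, nrow(st))
})
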