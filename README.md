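# quadgait

Phase-dependent gait-perturbation analysis for quadrupedal treadmill
locomotion.

When cutaneous afferents of the foot dorsum are activated — for example by
electrically stimulating the superficial peroneal nerve while a cat walks
on a treadmill — all four limbs adjust their timing, trajectories and
muscle activity, and the response depends on the phase of the step cycle
at which the stimulus arrives (the stumbling corrective reaction during
swing, the stumbling preventive reaction during stance). `quadgait` is an
R package for analyzing such experiments end to end, together with a
synthetic-session generator used to validate every stage by parameter
recovery.

The pipeline:

* **Gait events** — stance onset (toe-height threshold with persistence)
  and stance offset (most caudal toe position) per limb from marker
  trajectories; per-limb cycles with cycle, stance and swing durations
  (swing ≡ cycle − stance).
* **Phase classification and triads** — each stimulus is assigned to
  mid-stance, stance-to-swing, mid-swing or swing-to-stance from its
  normalized position in the ipsilateral cycle (configurable disjoint
  windows, stimuli outside all windows excluded), and the
  control/stimulated/post cycle triad is extracted for all four limbs.
* **Spatiotemporal metrics** — support-period decomposition (the nine
  categories of quadrupedal walking: four doubles, four triples,
  quadrupedal; canonical walking shows eight periods per cycle), step and
  stride lengths (stride = stance displacement + belt speed × swing
  duration), joint angles (hip/knee/ankle included angles) and maximum
  marker heights.
* **EMG** — 30–1000 Hz zero-phase band-pass, rectified low-pass envelope,
  double-threshold burst detection (median + k·MAD), burst duration and
  mean rectified amplitude normalized to the control cycle (= 100%).
* **Statistics** — per-animal triad means per cycle, Friedman
  repeated-measures rank test across (control, stimulated, post) per
  phase, Shapiro–Wilk normality (reported, not gating), Bonferroni-
  adjusted Wilcoxon post hoc comparisons against control, and group
  percent changes (mean ± SD of per-animal 100·(value − control)/control).

Results are tidy tibbles throughout, with `tidy()`/`glance()` methods and
ggplot2 helpers (`plot_phase_effects()`, `plot_support_periods()`,
`autoplot()`).

## Worked example

Simulate a seven-animal study with stimuli at mid-swing using the shipped
reference effect profiles (ipsilateral swing ×1.235, cycle ×1.060, toe
apex ×3.313, contralateral step length ×0.867), analyze it, and inspect
the ipsilateral temporal effects:

```r
library(quadgait)
library(dplyr)

cfg <- session_config(n_animals = 7, cycles_per_animal = 70,
                      stimuli_per_phase = 10, phase_targets = "mid_swing",
                      seed = 42,
                      perturbation_profiles = reference_phase_effects())
study <- simulate_study(cfg)
res <- analyze_study(study)

res$stats |>
  filter(variable %in% c("swing_duration", "cycle_duration"),
         limb == "ipsi_hind") |>
  select(phase, variable, n_animals, mean_control, mean_stim,
         pct_stim, friedman_p, p_stim_vs_control)
#>       phase       variable n_animals mean_control mean_stim pct_stim friedman_p
#> 1 mid_swing cycle_duration         7        0.979     1.036     5.83   0.000912
#> 2 mid_swing swing_duration         7        0.341     0.418    22.48   0.005063
#>   p_stim_vs_control
#> 1            0.0313
#> 2            0.0313
```

Reading the output: the group-mean ipsilateral swing duration rises from
0.341 s in the control cycle to 0.418 s in the stimulated cycle (+22.5%,
recovering the injected +23.5% within sampling error of 7 animals × 10
triads), the cycle lengthens by +5.8% (injected +6.0%), the Friedman test
across the three cycles is significant in both cases, and the
Bonferroni-adjusted Wilcoxon comparison of stimulated vs control gives
p = 0.031 — the smallest attainable two-sided value at n = 7, reached when
every animal shifts in the same direction.

`build_report(res$stats, "report/")` writes per-phase `effects_*.tsv`
tables and `stats.json`.

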