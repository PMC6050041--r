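# scsurround

Center–surround modulation analysis for two-photon calcium imaging of
visual neurons, built around the stimulus designs used to study contextual
motion processing in the superficial mouse superior colliculus. The package
is aimed at systems neuroscientists who record per-ROI fluorescence traces
while presenting a drifting-grating patch over each cell's receptive field
(RF) together with an independently moving annular surround, and who want a
tested, reproducible route from raw traces to population-level modulation
statistics. A synthetic recording generator with known ground truth makes
every stage of the pipeline testable without any raw data.

## What it computes

For each ROI the raw trace is converted to per-trial fractional
fluorescence change

    dF/F0 = (F - F0) / F0

where `F0` is the mean over a pre-onset baseline (1.25 s for gratings) and
`F` the mean over an indicator-specific response window (250 ms after onset
to 750 ms after offset for a fast indicator; shifted +375 ms for a slow
nuclear indicator). A cell is *responsive* when its mean dF/F0 for at least
one condition exceeds twice its pooled baseline SD.

Direction selectivity is the vector-sum index over the 8-direction
center-alone tuning curve `R_theta`:

    gDSI = | sum_theta R_theta * exp(i * theta) | / sum_theta R_theta

with negative responses rectified to zero, so `gDSI` lies in [0, 1].

Surround modulation at the preferred center direction is

    MI = (R_pref,C+S - R_pref,C) / (R_pref,C+S + R_pref,C),  clipped to [-1, 1]

negative for suppression, positive for potentiation. Significance per cell
uses a pooled-resampling bootstrap: the 4 + 4 trial values are pooled, 8
values are resampled with replacement 10,000 times, each resample is split
4/4 at random, and the observed mean difference is compared with the 95%
interval of the resampled differences (potentiated / suppressed /
non-modulated).

At the population level, aligned 9 × 9 response matrices (center × surround
direction, each including blank) yield tuning curves per center–surround
direction difference Δθ, and an ordinary least-squares fit of the
center-with-surround curve against the center-alone curve summarizes the
modulation geometry: slope < 1 with near-zero intercept is divisive
suppression, slope > 1 multiplicative potentiation. Further summaries cover
center-silent cells (responsive only to specific center–surround
combinations), linearity of center + surround summation, feature-contrast
surrounds (anti-phase, temporal frequency, static orientation), RF
centroids from flashing-square grids, depth profiles, and MI–gDSI
correlations per cell class.

## Worked example

Simulate a superficial, excitatory-only field of view and run the full
pipeline:

```r
library(scsurround)

protocol <- direction_contrast_protocol(n_repeats = 4, seed = 1)  # 81 conditions
cfg <- default_population_config()
cfg$p_inhibitory <- 0                            # excitatory-only field of view
cfg$depth_levels <- 25; cfg$depth_probs <- 1     # superficial imaging plane
cfg$depth_mod_factor <- 1; cfg$depth_kappa_factor <- 1
cells <- sample_population(120, cfg, seed = 2)
rec <- simulate_recording(protocol, cells, seed = 3)

results <- cell_summary(rec, seed = 4)
head(results[, c("cell_id", "gdsi", "preferred_direction", "mi_same",
                 "mi_opp", "category")], 5)
#>    cell_id  gdsi preferred_direction mi_same mi_opp       category
#> 1 cell0001 0.631                  45  -0.656  0.325    potentiated
#> 2 cell0002 0.582                 315  -0.460  0.267    potentiated
#> 3 cell0003 0.566                  45  -1.000 -1.000 non_responsive
#> 4 cell0004 0.379                 180  -0.417  0.240    potentiated
#> 5 cell0005 0.362                  90  -0.241  0.262    potentiated
```

Each row gives a cell's direction selectivity (`gdsi`), its preferred
direction, its modulation index for a same-direction (`mi_same`) and an
opposite-direction (`mi_opp`) surround, and its bootstrap-based category.
Here most cells are suppressed by the iso-directional surround
(`mi_same < 0`) and potentiated by the opposite surround (`mi_opp > 0`).

Population modulation geometry from the aligned matrices:

```r
mats <- response_matrices(build_response_table(rec))
keep <- results$cell_id[results$responsive_center]
aligned <- lapply(keep, function(id)
  align_matrix(mats[[id]],
               results$preferred_direction[results$cell_id == id]))
slopes_vs_delta_theta(aligned)
#>   delta_theta slope intercept r_squared slope_ci_lo slope_ci_hi n_points
#> 1           0 0.490   0.00496     0.998       0.470       0.509        8
#> 2          45 0.841   0.01409     0.999       0.816       0.865        8
#> 3          90 1.161   0.02486     1.000       1.136       1.186        8
#> 4         135 1.389   0.01888     0.999       1.349       1.429        8
#> 5         180 1.613   0.01383     0.999       1.575       1.652        8
```

The slope rises monotonically with the center–surround direction
difference — divisive suppression (slope ≈ 0.49) by a same-direction
surround grading into multiplicative potentiation (slope ≈ 1.61) by an
opposite surround — recovering the generator's modulation law (slopes
0.50 / 1.17 / 1.63 at Δθ = 0 / 90 / 180) from raw simulated traces. More
strongly tuned cells are potentiated more:

```r
mi_gdsi_correlation(results[results$responsive_center, ], surround = "opposite")
#> $r 0.54   $p 3.3e-06   $n 65
```

## Layout

- `R/` — protocols, synthetic generator, trace processing, RF mapping,
  tuning/modulation statistics, surround analysis, population summaries.
- `tests/testthat/` — unit, property and end-to-end recovery tests (all
  fixtures generated in code).
- `vignettes/center-surround-analysis.Rmd` — the methods vignette: model,
  assumptions, parameter choices and limitations.
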