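---
title: "Center-surround modulation analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-surround modulation analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsurround)
```

This vignette documents the analysis model implemented by `scsurround`,
the assumptions behind it, the tunable parameters and their defaults, what
the synthetic data generator does and does not emulate, and the numerical
conventions adopted where the underlying procedures leave choices open.

## The measurement model

A two-photon experiment in this design presents a drifting-grating patch
over the pooled receptive fields (RFs) of the imaged neurons, plus an
annular surround whose motion direction (or phase, temporal frequency, or
static orientation) varies independently of the center. The canonical
direction-contrast design crosses 8 center directions plus blank with 8
surround directions plus blank: 81 unique conditions, presented at least 4
times each in seeded pseudo-random order, 2 s per stimulus with a 5 s gray
inter-trial interval. Feature-contrast sets use 8 (anti-phase), 16
(temporal-frequency) and 25 (static-orientation) conditions; RF mapping
flashes a black square over a 6 x 6 grid of 5 degree squares (1 s on, 3 s
off).

Per trial, activity is quantified as `dF/F0 = (F - F0) / F0`, with `F0`
the mean fluorescence over a 1.25 s pre-onset baseline (0.75 s for flashed
squares) and `F` the mean over a response window from 250 ms after onset
to 750 ms after offset (gratings) or 350 ms after offset (squares). For a
slow nuclear indicator both response-window edges shift forward by 375 ms.
These windows are the package defaults (`default_windows()`); any
`window_spec()` can be substituted.

Three window conventions needed a decision:

* **Frame membership.** A frame belongs to a window when its acquisition
  midpoint falls in the half-open interval `[start, end)`. At 8.079 Hz the
  windows are never frame-aligned, and the midpoint rule makes membership
  unambiguous and deterministic.
* **Responsiveness.** "Mean dF/F0 more than two SDs above baseline" is
  made dimensionally coherent by expressing the baseline SD in dF/F0
  units: the pooled (root-mean-square across all the cell's trials) value
  of `sd(baseline frames) / F0`, compared against the across-repeat mean
  dF/F0 per condition. Pooling across trials (rather than per-trial SDs)
  stabilizes the noise estimate at 4 repeats; the choice is exposed via
  the function arguments. The criterion is deliberately conservative:
  averaging over repeats shrinks the mean's noise well below the
  per-frame baseline SD, so false positives on pure-noise cells are rare
  (the test suite measures this against a direct Monte-Carlo oracle).
* **Negative dF/F0** values are retained through all averaging. Slow
  indicators whose decay outlasts the inter-trial interval produce
  negative values at non-responsive conditions; clipping happens only
  inside the modulation index, where the published definition requires it.

## Tuning and modulation statistics

**gDSI** is the magnitude of the response-weighted vector sum over the
center-alone tuning curve divided by its scalar sum. Negative entries are
rectified to zero first; this keeps the index in [0, 1] and is the
behavior most users expect, but rectification is configurable
(`rectify = FALSE`) because it can overestimate selectivity when a slow
indicator drives baselines negative. An all-zero rectified curve leaves
gDSI undefined (`NA`), and such cells are excluded from selectivity
analyses rather than assigned 0.

**Preferred direction** is the center direction with the peak mean
center-alone dF/F0. Center-silent cells - responsive to neither center
alone nor surround alone but responsive to specific center-surround
combinations - take the center direction of their peak center-surround
combination instead. Ties break toward the lowest direction label purely
for determinism.

**Modulation index** `MI = (R_CS - R_C) / (R_CS + R_C)` is clipped to
[-1, 1]. When the denominator is exactly zero the index is defined as the
sign of the numerator (0 if both responses are zero); this convention only
matters on degenerate synthetic input but keeps the function total.

**Bootstrap classification.** The 4 + 4 trial values of the two compared
conditions are pooled; 8 values are drawn with replacement 10,000 times
and each draw is split at random into two groups of 4 whose mean
difference forms the null distribution (because the resampled values are
exchangeable, taking the first four against the last four of each draw is
such a random split). The observed difference is compared with the
empirical 2.5% and 97.5% quantiles (linear interpolation). A property
worth knowing: resampling from the pooled 8 values slightly understates
the null variance relative to a true permutation null (the pool's
variance enters with a factor (2n-1)/2n), while the observed-difference
contribution to the pool variance pushes the other way. The net effect,
measured by the test suite and the acceptance script on exchangeable
Gaussian nulls, is a non-modulated rate of about 94% at a nominal 95% -
within 1.5 percentage points of nominal, and slightly anti-conservative
rather than conservative.

**Categories.** For the population taxonomy at the preferred center with
opposite surround, cells responsive to no condition - and cells responsive
to the surround alone but nothing else - are `non_responsive`; all others
carry their bootstrap class.

## Population modulation geometry

Each cell's 81 condition means form a 9 x 9 matrix (center x surround,
blank last). Matrices are circularly shifted along both direction axes so
the preferred center direction sits at relative 0; the blank row/column
stays fixed and the multiset of entries is conserved. Population tuning
curves are across-cell means per center-surround relationship:
center-alone, and each folded direction difference
delta-theta = min(|theta_c - theta_s|, 360 - |theta_c - theta_s|).
Folding averages the clockwise and counterclockwise off-diagonals at 45,
90 and 135 degrees; the sign of the offset is deliberately discarded, as
only the magnitude of the direction contrast is analyzed.

The modulation fit regresses the 8-point center-with-surround curve on the
8-point center-alone curve by ordinary least squares with intercept. The
blank-center point is excluded: the fit describes how the surround
transforms the *tuning curve*, and the gray-screen response carries no
direction information. Slope confidence intervals use t-based standard
errors on 8 points. Fits are run on raw population-mean curves; per-cell
normalization before averaging is available upstream but off by default,
since the raw and normalized routes lead to the same qualitative
conclusions and raw units keep intercepts interpretable (fractional
dF/F0). Per-cell fits apply the same regression within each cell and
filter on R^2 >= 0.5; cells whose center-alone curve has (near-)zero
variance are flagged rather than silently dropped, because a flat
predictor makes the slope meaningless.

## Receptive-field mapping

RF centers use the response-weighted center of mass over *responsive* grid
locations (same 2-SD criterion, applied per location), excluding
non-responsive locations from the sums. Coverage by the grating patch is
an inclusive 10 degree radius test. The per-field-of-view dispersion of
centroids is the root-mean-square distance from the mean centroid - a
single rotation-invariant scalar chosen as the "2D standard deviation";
RF "area" is reported as (number of significant squares) x 25 deg^2.
Both are labeled conventions in the output, not fitted quantities.

## The synthetic generator

The generator exists so that every pipeline stage can be exercised against
known ground truth. Each simulated neuron has:

* **Direction tuning**: von Mises in direction (period 360 degrees),
  normalized to 1 at the preferred direction, concentration kappa drawn
  from a Gamma(2, rate 1.3) distribution. The tuning-curve family is a
  modeling choice - only one concentration parameter, standard in the
  field; nothing downstream depends on this exact form.
* **Surround modulation law**: an affine map `R_CS = a(dtheta) * R_C +
  b(dtheta)` per folded direction difference. Excitatory defaults use
  slope/intercept pairs (0.50, 0.0048), (1.17, 0.0254), (1.63, 0.0155) at
  0/90/180 degrees - fractional dF/F0 units, i.e. 0.48/2.54/1.55 in %
  units - with both slope and intercept linearly interpolated at 45/135
  (the intermediate levels are otherwise unconstrained, and linearity is
  the minimal assumption). Inhibitory defaults have slopes below 1
  everywhere, smallest at 180 degrees, zero intercepts; a per-cell
  monotonicity repair guarantees the opposite surround is most
  suppressive for every cell, not just on average.
* **Center-silent cells** (23.6% of excitatory cells by default): zero
  center-alone and surround-alone response, and an emergent
  center-surround response `b(dtheta)` rising with dtheta. The emergent
  response is additionally shaped by the cell's von Mises profile over
  center direction, so that a center-silent cell *has* a preferred center
  direction for the downstream rule to recover; a pure intercept-only law
  would make the preferred-direction assignment arbitrary.
* **Class structure**: 45% inhibitory; surround-alone responsiveness
  53.8% (inhibitory) vs 10% (excitatory); inhibitory RF centroids scatter
  twice as widely as excitatory ones; 80.6% of center-silent cells have
  mappable RFs.
* **Depth structure**: four imaging depths (25, 60, 120, 180 um,
  equiprobable). Tuning concentration scales by 1/0.8/0.6/0.4 across
  depths, and the potentiating part of the excitatory law (a - 1 where
  positive) scales by 1/0.6/0.1/-0.4, so potentiation grades into
  suppression at depth. The printed law values hold exactly at the
  superficial level; the depth gradients are qualitative config values,
  not calibrated claims.
* **Selectivity coupling**: per-cell modulation strength couples to
  tuning strength s = kappa/(kappa + 2) - positively for excitatory
  potentiation, negatively for the inhibitory opposite-surround slope
  (and positively for the inhibitory same-surround slope) - giving the
  class-specific signs of the MI-vs-gDSI correlations and the
  gDSI-stratified contrasts.
* **Indicator kinetics**: the trial time course is a boxcar of the
  stimulus duration convolved with a difference-of-exponentials kernel;
  fast defaults 50 ms rise / 600 ms decay, slow nuclear 400 ms / 3 s
  (the slow indicator is only constrained to be substantially slower;
  these constants are free choices). The template is normalized so its
  mean over the indicator's own default response window is 1, which makes
  the window-averaged dF/F0 of a noiseless trial equal the generative
  expected response up to quadrature (the round-trip tests bound the
  error at 2%). The slow indicator's 3 s decay exceeds the 5 s
  inter-trial interval's headroom, so its baselines are contaminated by
  the preceding trial and negative dF/F0 values arise naturally, as with
  real nuclear indicators.
* **Noise**: additive i.i.d. Gaussian on the raw trace, SD
  `noise_sd * baseline_F` per frame (default 0.04 dF/F0 units).
  Trial-to-trial gain variability, correlated noise, neuropil
  contamination, motion artifacts, eye movements and running-state
  modulation are *not* modeled; spiking and stimulus rendering are not
  simulated (condition labels map directly to expected responses).
  Passing tests on this generator therefore demonstrate correctness of
  the analysis given its statistical assumptions - not robustness to the
  full artifact structure of in vivo recordings.

Determinism: every sampling function takes a seed, uses an isolated RNG
scope, and restores the caller's RNG state; identical (config, seed) give
bit-identical populations and recordings.

## Problem sizes and runtime envelope

The test suite simulates at sizes chosen to make sampling error small
relative to the tested margins while keeping a full run in tens of
seconds: 48-cell noiseless populations for structural checks, a 260-cell
mixed population for class/depth summaries, a 450-cell superficial
excitatory population at default noise for end-to-end slope recovery
(which recovers 0.50/1.17/1.63 within a few percent), 400 null cells for
the responsiveness false-positive check, and 2000-4000 null trial pairs
at 10,000 resamples for bootstrap calibration.

## Known limitations

* The affine surround law is the generator's ground truth, so recovery
  tests validate the estimator, not the biological adequacy of an affine
  description.
* The responsiveness criterion's false-positive rate depends on window
  lengths and frame rate; at very low frame rates the windows cannot be
  resolved and the simulator refuses to run rather than degrade.
* `gDSI` on 8 directions saturates for very sharp tuning; comparisons
  across kappa are monotone but not linear.
* The bootstrap classifier is slightly anti-conservative (about 6% type I
  at nominal 5%; see above) - a property of the pooled-resampling
  construction itself, reported rather than corrected, because the
  construction is the method under study.
* Serialization uses CSV/JSON directories; traces for large sessions are
  bulky in text form. The generator's determinism makes regeneration from
  (config, seed) the preferred route for synthetic data.
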