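---
title: "Modelling neutrophil migratory decision-making in a dual-gradient chip"
author: "muc3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neutrophil migratory decision-making in a dual-gradient chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muc3)
```

## The assay being modelled

The competitive chemotaxis chip places neutrophil-like cells (dHL-60) in a
central loading channel flanked by two chemoattractant reservoirs: fMLP
(10 nM, an end-target, bacterial-mimetic peptide) on one side and LTB4
(100 nM, an intermediary inflammatory lipid) on the other. Ten straight
migration channels per side (900 um long, 10 x 10 um cross-section) connect
the loading channel to each reservoir, and vertical "maze" ladder rungs
join adjacent channels, carrying a 10-fold weaker gradient. Cells must
decide which gradient to follow; time-lapse imaging at 2.5-min intervals
for 5 h yields single-cell trajectories from which migratory phenotypes are
quantified. The biological question is how conditioning with
lipopolysaccharide (LPS) — a super-low overnight dose (1 ng/mL) versus a
high dose (100 ng/mL) — reprograms this decision relative to unstimulated
cells.

The package provides an end-to-end in-silico counterpart: gradient physics,
an agent-based track generator under calibrated priming presets, a
synthetic imaging and tracking pipeline, and the full metric suite.

## Gradient physics

Chemoattractant transport along a migration channel is modelled as 1-D
diffusion, `dc/dt = D d2c/dx2`, with the reservoir end held at the loading
concentration and the loading-channel end treated as a perfect sink (the
loading channel is bathed in ~4 mL of media versus 10 uL reservoirs — about
a 10^5 volume ratio — so the sink is the physically sensible default; a
well-mixed finite bath is available as an option). Diffusion coefficients
come from the Stokes–Einstein relation with the globular hydrodynamic
radius scaling `r = 0.066 nm x MW^(1/3)`, at 310 K in water
(`eta = 6.913e-4 Pa s`): `D(438 Da) = 655 um^2/s` for fMLP and
`D(336 Da) = 716 um^2/s` for LTB4.

Time stepping is Crank–Nicolson (`dx = 10 um`, `dt = 1 s`) with two
implicit-Euler start-up steps to damp the initial boundary discontinuity,
making the scheme unconditionally stable and monotone in practice; an
explicit scheme is provided for comparison and refuses to run when
`D dt/dx^2 > 1/2`. The solver agrees with the analytic Fourier-series
solution to better than 1e-3 of the reservoir concentration at all checked
times, and the steady profile is linear to < 0.5%.

A gradient counts as *formed* when the profile is uniformly within 5% of
its steady state (the source text gives no criterion; 5% matches the
reported "equal within 5%" slope comparison). Under the defaults both
gradients form in about 6 min — consistent with the reported < 15 min —
and remain at steady state through the full 5-h experiment. Because both
profiles are linear after formation, their reservoir-normalized slopes
agree to well under 5%.

Inside maze rungs the *gradient* (not the concentration) is attenuated
10-fold, following the device description; whether that factor arises from
rung geometry or was measured is not stated in the source, so it is an
explicit geometry parameter (`maze_attenuation`).

## The migration model

No cell-behaviour model is given in the source; the generator here is the
package's own construction — the minimal biased persistent random walk able
to express all five reported phenotypes. Per 2.5-min step (one imaging
frame):

* **Channel entry.** A motile loading-channel cell commits to a side with
  per-minute hazard `h0 (1 + bias_side * S_side)`, where
  `S_side = |d(c/c0)/dx| * L` is the normalized gradient steepness from the
  solved field (~1 once formed, 0 without chemoattractant) and
  `h0 = 0.004/min` is the gradient-free baseline. It then walks to the
  nearest channel mouth on that side at its migration speed, entering only
  when the first 12 um of the channel are free (the 10-um mouth admits one
  cell at a time).
* **Channel transit.** Speed is drawn per cell from a side-specific normal
  distribution (floored at 0.5 um/min), with small step-to-step noise.
  Direction flips away from the reservoir with probability `reversal_prob`
  per step and realigns up-gradient with probability 0.5 per subsequent
  step, so one reversal produces a short backward excursion — the
  oscillatory phenotype is the accumulation of such excursions, without an
  explicit state machine.
* **Maze branching.** Crossing a rung junction, the cell branches into the
  rung with probability `maze_entry_weight / maze_attenuation` (the rung's
  relative gradient steepness weighted by the preset), then performs an
  unbiased walk along the rung until it rejoins a channel. Maze visits are
  the "lost", non-directional phenotype.
* **Absorption.** Cells reaching a reservoir stay there; cells retreating
  past the mouth rejoin the loading pool and may re-enter.
* **Excluded volume.** Cells never overlap: seeding enforces a 12-um
  centre-to-centre spacing, a soft-exclusion pass keeps that spacing in the
  2-D compartments, and channels are single file — a trailing cell cannot
  pass the cell ahead (queueing). These constraints matter doubly: they are
  physically right for ~10-um nuclei in 10-um channels, and they make the
  rendered image stacks trackable, since permanently merged nuclei are
  unresolvable for any spot tracker.

Without chemoattractant the same machinery runs with `S = 0`: a
`spontaneous_fraction` of cells is motile and enters channels at the
baseline hazard only.

Runs are bit-reproducible given `(preset, seed)`.

## Priming presets and calibration

The three packaged presets (`lps_presets()`) encode the unstimulated,
super-low-dose (1 ng/mL) and high-dose (100 ng/mL) conditioning states.
Their parameters were fitted by grid search (`calibrate_preset()`, which
minimises summed squared relative error over simulated replicates) against
the published per-condition summary statistics: endpoint percent migrated
per reservoir, maximum 1-h accumulation rates, mean in-channel velocities
per side, spontaneous migration fractions, and the decision ratios (2:1
naive, ~1:1 super-low, 10:1 high dose). The default experiment is 500
cells for 300 min at 2.5-min frames, three replicates — percentages are
scale invariant in this regime, so the reduction from the ~500,000 cells
loaded in the wet assay only adds sampling noise.

Calibration notes, in the package's own words:

* `speed_mean_*` are the underlying walk speeds; the *measured* in-channel
  velocity is slightly lower because single-file queueing delays trailing
  cells. The presets are calibrated so the measured means match the
  published ones (10.51 and 10.23 um/min toward fMLP for unstimulated and
  high dose; 8.54 for super-low dose).
* Between-cell speed spreads are narrower than the published population
  SDs (~2 vs ~3-4 um/min). The published SDs fold in within-cell and
  measurement variance that the per-cell summary statistic averages out;
  the narrower spreads keep the 3-replicate mean velocity stable.
* The super-low preset cannot simultaneously reproduce every published
  number for that condition under single-file physics: reproducing the
  LTB4 endpoint (18.5%) together with its steep accumulation rate
  (10.7 %/h) requires concentrated LTB4 entries and fast, narrow transit,
  which leaves the condition's fMLP endpoint at ~11% (published 16.1 +/-
  3.3) and its LTB4 velocity at ~10.5 um/min (published 9.58). The
  reported-rate and velocity-toward-fMLP quantities were prioritised.
* Classification counts are treated as trend targets only (the source's
  own counts disagree internally between text and captions). The presets
  reproduce the lost-cell ordering (super-low >> high > unstimulated) and
  the higher oscillatory counts after super-low priming; queueing inflates
  the high-dose oscillatory count above its published share, a known
  limitation of coupling dense traffic to the direction-change rule.

## Metric definitions

All metrics operate on the shared track schema (`cell_id`, `frame`,
`t_min`, `x_um`, `y_um`, `region`), whether tracks come from the simulator
or from images.

* **Percent migrated**: cells in the chemoattractant reservoir (or
  migration channels) at each frame, divided by the *time-averaged*
  loading-channel count over the whole experiment, times 100. The
  denominator deliberately includes frames after cells have emigrated,
  following the metric's published definition literally.
* **Rate of accumulation**: the maximum over all sliding 1-h windows of
  the OLS slope of the percent-migrated series, in %/h — the slope of the
  hour of fastest accumulation.
* **Cell velocity**: path length over elapsed time across consecutive
  same-side in-channel/in-maze samples (scope `"whole_track"` available).
  Gap-bridged segments are excluded (a straight line across a detection
  gap under-measures path), as are cells with under 20 um of in-channel
  path, which did not meaningfully migrate.
* **Direction changes**: per-axis displacement components below a 2-um
  jitter floor are ignored; a change is a sign flip between consecutive
  retained steps on x or y. The floor is below half a channel width, so
  lateral centroid jitter inside a channel cannot register as a turn.
* **Classification** (non-exclusive): *non-directional/lost* = visited a
  maze rung; *oscillatory* = at least 3 direction changes; *directional* =
  left the loading channel with neither other flag.
* **Decision ratio**: endpoint percent toward fMLP over endpoint percent
  toward LTB4, at the final frame (the source does not state the
  timepoint; 5 h is the natural endpoint).
* **Spontaneous migration**: percent of cells that ever entered a
  migration channel during a no-chemoattractant run, with the same
  denominator, reported at the end of the run.

Group comparisons use the unpaired equal-variance Student's t-test at
alpha = 0.05, matching the original analysis; Welch and multiple-testing
corrections are available but off by default, with the deviation from
standard practice inherited from the source's statistical treatment.

## Imaging and tracking

`render_frames()` emulates nuclear-stain time-lapse imaging: each cell is
an isotropic Gaussian spot (default sd 0.9 px at 4 um/px, i.e. a ~8.5-um
FWHM nucleus) on a constant background with Poisson shot noise and
Gaussian read noise. `detect_spots()` runs difference-of-Gaussians blob
detection with sub-pixel quadratic refinement (~0.3 um localisation error
on the defaults). `link_spots()` links detections with a
constant-velocity-predicting greedy assignment: exponentially smoothed
per-track velocity gives the predicted position; unambiguous short-range
pairs are locked first; the remainder is solved per connected component of
the feasibility graph by exhaustive minimum-cost assignment with miss
penalties. The displacement ceiling is 50 um per 2.5-min frame (20
um/min), covering the upper tail of the observed velocity distributions;
gaps up to 2 frames are bridged.

On rendered control fixtures (100 cells, 121 frames) the tracker recovers
98-100% of detections with >= 95% of tracks kept under a single identity,
and the metric pipeline closes: percent migrated, velocity means and
classification counts computed from tracked images match the ground-truth
values within a few percent. The super-low-dose phenotype is intrinsically
harder — frequent reversals and maze transits create genuinely ambiguous
assignments — and identity recovery drops to ~90% there, although the
derived metrics still close because fragments measure the same speeds and
the same reservoir occupancy.

## Numerical and design choices

* Coordinates: origin at the loading-channel centre, +x toward the fMLP
  reservoir; um and minutes throughout.
* Region boundaries resolve toward the distal structure (mouth -> channel,
  reservoir mouth -> reservoir, channel/rung junction -> rung). Tracked
  centroids may be snapped onto the nearest structure within a small
  tolerance, since localisation noise can place a cell just outside the
  10-um channel.
* The solver records profiles at 1-min resolution, which quantises
  formation times upward by at most one minute.
* Degenerate inputs are explicit: zero-concentration fields are flat and
  "formed" at t = 0; decision ratios with a zero denominator return `Inf`
  (flagged); velocity is `NA` for tracks with fewer than two in-scope
  samples and such cells are excluded from summaries.

## What passing tests do and do not show

The generator reproduces the *published summary statistics* of the wet
assay under a minimal behavioural model — it demonstrates that the metric
suite and pipeline are implemented faithfully and that a biased persistent
random walk with excluded volume suffices to express the reported
phenotype shifts. It does not validate the model mechanistically: there is
no receptor signalling, no cell-cell cross-talk (explicitly outside the
source's own scope), no secretion, division or death, and real nuclei are
not isotropic Gaussians. Phenomena at loading densities far above the
calibrated regime (mouth saturation) and the exact published population
SDs of velocity are outside what the calibration claims.

## A small worked example

```{r example, eval = FALSE}
fields <- default_fields(t_end = 300)
run <- simulate_experiment(lps_presets()$unstimulated, fields = fields,
                           n_cells = 500, duration = 300, seed = 1)
m <- migration_metrics(run)
m
plot(m)
```
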