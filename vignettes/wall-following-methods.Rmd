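---
title: "Quantifying wall-following behaviour: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wall-following behaviour: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallfollowr)
```

## The behavioural measurement model

Wall-following (thigmotaxis) is the tendency of an animal to travel
close to the boundary of its habitat; in cave-adapted fishes it is a
prominent, non-visually guided exploration strategy. `wallfollowr`
scores it from centroid tracks recorded at 25 samples/s in a
rectangular arena whose default footprint is 45 × 28 cm. All positions
are arena-frame centimetres (origin bottom-left), and all distance and
speed indicators are normalised by the individual's standard length
(SL), so that individuals of different size are comparable.

The *near-wall belt* is the set of points within 0.5 SL of the nearest
wall, measured as `min(x, W - x, y, H - y)`. Using the minimum wall
distance makes the belt a rectangular annulus in which each corner
region belongs to the belt exactly once. Zone and belt boundaries are
*closed* (inclusive): a point exactly at the threshold is inside. This
convention makes membership deterministic for coordinates that land
exactly on a boundary, which happens routinely with synthetic tracks.

A *bout* opens when the track enters the belt and closes when it exits.
A bout qualifies as a *wall-following event* only when the path
accumulated over in-belt sample intervals reaches 2 SL. Sub-threshold
visits contribute nothing to any indicator: the minimum-path gate is
what distinguishes deliberate wall-following from incidental passes
near a wall. Six indicators summarise a trial; their exact accounting
rules are:

* **WF-Distance** (SL): summed in-belt path of qualifying events.
  An interval contributes when both endpoints are in the belt.
* **WF-Frequency** (count): number of qualifying events. The permissive
  alternative — counting every belt entry — is available via
  `segment_wf_events(all_entries = TRUE)`; we default to the qualifying
  reading because only gated bouts are recorded as wall-following
  behaviour in the first place.
* **WF-Time** (%): summed event duration over testing time. Resting
  frames inside an event count toward its duration (the fish is still
  station-holding at the wall).
* **WF-Resting Time** (s): total time below the immobility threshold
  over the *whole* assay, not only in the belt.
* **WF-Speed** (SL/s): event path divided by event *mobile* time.
  Excluding resting time from the denominator makes this an average
  swimming speed, not an average occupancy speed.
* **WF-Max Speed** (SL/s): maximum per-interval speed over the whole
  assay, per its conventional definition as a whole-trial maximum.

Speeds below 0.2 cm/s are classed as resting. The threshold applies to
the raw per-interval speed with no hysteresis: a single printed
threshold is easier to reason about than a two-threshold scheme, and at
25 Hz chatter around the threshold has negligible effect on the
indicators (resting time is a sum, and events are gated by path, not by
contiguous mobility).

Heading is estimated as the direction of the central-difference
displacement over a 5-sample (0.2 s) window. Tracking provides only the
centroid, so the body midline needed for approach angles is
operationalised as this smoothed motion direction; headings are
undefined while resting.

## Stimulation assays

Landmark (5 min) and vibration (3 min) assays place a stimulus at the
arena centre: a 5 cm diameter opaque cylinder, or a 40–50 Hz vibration
source whose physical footprint defaults to the same 2.5 cm radius
because pump geometry is rig-specific. The *stimulation range* is the
10 × 16 cm axis-aligned rectangle around the stimulus centre (16 cm
along x). S-indicators mirror the wall-following set without a path
gate: every zone entry is a bout.

The approach *distance* models the fish as a 1-D segment of length SL
centred on the centroid and aligned with the heading; the reported
value is the shortest distance from that segment to the stimulus
boundary circle, clamped at zero on overlap, in SL. The approach
*angle* is the unsigned angle (0–180°) between the heading and the
bearing to the stimulus centre. Only the first three approach bouts are
recorded. Each bout is measured at its frame of minimal body-to-
stimulus distance among frames with a defined heading; measuring at the
entry frame instead is available (`measure_at = "entry"`). We default
to closest approach because it is well-defined for every bout shape and
does not depend on how the zone boundary happens to be crossed; when no
frame of a bout has a defined heading the nearest mobile frame is used
and the record is flagged.

## The swim simulator

`simulate_trajectory()` generates synthetic trials from a
boundary-attracted correlated random walk, giving the package a fully
controlled stand-in for tracked recordings:

* **Turning noise.** Wrapped-normal heading increments with
  concentration κ = 8 (sd ≈ 0.35 rad per 0.04 s step) — a standard
  correlated-random-walk choice producing a heading decorrelation time
  of a few tenths of a second.
* **Speed.** Per-step lognormal draws with arithmetic mean
  `speed_mean_sl_s × SL` cm/s and log-sd 0.35, spanning roughly
  0.3–0.7 SL/s across morph presets.
* **Wall attraction.** Inside a sensing range of 1 SL the heading
  receives a torque `β dt sin(θ* − θ)` toward a target direction θ*
  given by the wall tangent (the orientation closer to current travel)
  plus an inward/outward correction `2 (d − d₀)/sense` that regulates
  the distance d to the nearest wall around a preferred offset
  d₀ = 0.25 SL (mid-belt). Tangent alignment alone orients the fish
  parallel to the wall but does not hold a distance; the offset
  correction is what turns alignment into sustained wall-following. β
  is the single attraction gain graded across morphs.
* **Stimulus bias.** An optional torque of gain γ toward the stimulus
  centre.
* **Move/rest switching.** A two-state Markov chain with entry rate
  `rest_on_rate_hz` and exit rate `rest_off_rate_hz`; the stationary
  resting fraction is on/(on + off). Resting freezes position and
  heading.
* **Boundaries.** Specular reflection, so path lengths remain
  well-defined and positions never leave the arena.

Morph presets calibrate `(speed, β, rest rates)` per eye morph: mean
speeds 0.52 / 0.45 / 0.36 SL/s for eyeless / micro-eyed / normal-eyed
(the observed per-morph wall-following speeds), β = 5 / 2.5 / 1.2, and
resting rates increasing toward the normal-eyed morph. These constants
are stored as data (`.morph_calibration`), not buried in code. The
presets reproduce the qualitative gradient — eyeless fish wall-follow
farther, longer and faster — with comfortable statistical separation at
30 trials per morph.

What the simulator does *not* emulate: hydrodynamics and lateral-line
sensing, burst-and-glide gait structure, 3-D excursions, tracking noise
and identity swaps, and arena inhomogeneities. Passing tests on
simulated data therefore validate the *scoring and statistics*, not any
claim about real fish; with real exports the same pipeline applies
unchanged, but event counts will additionally reflect tracking-quality
artefacts that `fill_gaps()` only partially absorbs.

## Trajectory repair

Tracking gaps ≤ 0.5 s are filled by linear interpolation and flagged;
longer gaps split the track into independent segments, and analysed
time excludes the gap. Half a second at 25 Hz (12 samples) is short
enough that linear interpolation cannot fabricate a wall visit of any
consequence, while longer dropouts usually mean occlusion or tracker
loss, where interpolation would invent behaviour. Event segmentation,
kinematics and bout detection never cross segment boundaries.

## Statistics

* **Kruskal–Wallis** with mid-ranks and the tie-correction factor
  `1 − Σ(t³ − t)/(N³ − N)`, referred to χ²(k−1).
* **Dunnett T3**: pairwise Welch statistics with Satterthwaite df,
  adjusted over the m = k(k−1)/2 comparisons with the studentized
  maximum-modulus tail evaluated under the independence approximation,
  which coincides with a Šidák correction of the two-sided Welch p.
  The exact SMM quantile accounts for the correlation structure of the
  comparisons; the independence form is slightly conservative and is
  the documented fallback.
* **Negative-binomial regression** (log link) for the over-dispersed
  WF-Distance response, fitted by ML via `MASS::glm.nb` with predictors
  standardized to unit variance. WF-Distance is continuous in SL units;
  it is rounded to the nearest integer for the NB response, the
  smallest-intervention discretisation consistent with fitting a count
  model to it. The package fits fixed-effects models on per-trial rows;
  repeated-measures random effects (individual identity, testing time)
  are deliberately out of scope, a documented divergence from
  mixed-model practice on such designs — with the consequence that
  standard errors ignore within-individual correlation.
* **AICc full model averaging**: all predictor subsets (or an explicit
  candidate list), AICc = −2logL + 2k + 2k(k+1)/(n−k−1) counting the
  dispersion parameter in k, retention at ΔAICc ≤ 2, Akaike weights,
  and full averaging in which a model omitting a term contributes a
  zero estimate. Adjusted SEs use the standard multimodel formula and
  95% CIs the normal quantile; terms whose CI excludes zero are flagged
  important. Candidates that fail to converge (typically because the
  conditional distribution is equidispersed, driving the NB size
  parameter to infinity) are dropped with a warning rather than
  aborting the average.

## Phylogenetic signal

Species are the unit of the comparative stage; per-trial indicators are
aggregated to species means. Pagel's λ scales the off-diagonal entries
of the Brownian covariance `C` (shared root-to-MRCA path lengths);
`estimate_lambda()` maximises the profile likelihood over λ ∈ [0, 1],
with the GLS mean and the ML rate σ² concentrated out in closed form at
each λ and a 21-point multistart grid guarding against local optima
before bounded refinement. The [0, 1] bound matches the convention of
the standard comparative-methods tooling even where larger λ would keep
`C(λ)` positive definite; boundary fits are reported as exactly 0 or 1.
On a star phylogeny the likelihood does not depend on λ and the
estimate is 0 by convention. The LRT against λ = 0 reports the plain
χ²(1) p (conservative at the boundary) alongside the 50:50
point-mass-mixture alternative. PGLS uses the same profiled covariance
with λ fixed or jointly ML-estimated.

The fixture chronogram bundled with the study generator is a
*synthetic* ultrametric 13-species tree with four labelled clades
(A–D), constructed so the stygomorphic species cluster in clade B —
plausible but hand-written; analyses of real data should supply their
own dated tree in Newick form.

## Numerical conventions and degenerate inputs

* Coordinates up to 1 cm outside the arena are clamped (tracking
  jitter); farther excursions are validation errors listing offending
  rows. Files with more than 50% gap samples are rejected.
* Per-sample time credit: each sample carries the duration of its
  preceding interval; the first sample of a segment carries zero, so
  segment times sum exactly to the segment span.
* A trial whose mobile time is below 10% of the assay is dropped and
  logged by `run_study()`, mirroring the usual removal of
  fully-stationary videos; the threshold is configurable.
* All-identical samples give H = 0, p = 1 in the rank test; zero
  variance in both groups gives a zero T3 statistic; an all-zero count
  response is a fitting error.
* Simulator, trait simulation and study generation take explicit
  integer seeds and restore the caller's RNG state, so embedding them
  in other stochastic code is side-effect-free.

## Problem sizes used by the checks

The bundled verification suite works at desk scale by choice: oracle
equivalence on 100 simulated 600 s trials; the morph-gradient check at
30 trials per preset (seeds 1–30); λ recovery on a 64-tip balanced tree
with 200 Brownian replicates against tip-shuffled controls; NB recovery
at n = 500 over 100 replicates; and the acceptance script's study at 30
trials per morph. These sizes give stable Monte-Carlo behaviour while
keeping a full run in minutes on one core.

## Known limitations

* Fixed-effects NB regression understates uncertainty for repeated
  measures of the same individual (see above); marginal/conditional R²
  for mixed models is correspondingly not computed.
* The T3 adjustment uses the independence (Šidák) form of the SMM tail.
* Approach geometry relies on the smoothed motion direction as a body
  axis; during sharp turns the true midline deviates from it.
* The belt/zone boundary convention is inclusive; indicator values at
  exactly-threshold geometries depend on that choice.
* λ estimation assumes a single trait observed without error at each
  tip; with three individuals per species, species means carry sampling
  noise that biases λ̂ downward.
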