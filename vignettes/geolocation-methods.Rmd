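---
title: "Hidden Markov geolocation and movement metrics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden Markov geolocation and movement metrics: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basstrack)
```

`basstrack` reconstructs the daily positions of demersal fish carrying
archival (data storage) tags from their depth and temperature records, and
computes the movement-ecology summaries built on those reconstructions:
residency indices from acoustic detections, site fidelity, migration-strategy
classification, and seasonal movement networks. This vignette is the
package's own account of the models it implements, the numerical choices
behind them, and what its synthetic data can and cannot show.

## The geolocation model

A fish's unknown daily position is a hidden state on a regular lat/lon grid
restricted to water cells. Each day $t$ contributes an observation
likelihood over cells, and consecutive days are linked by a movement kernel;
filtering and smoothing are the standard scaled forward-backward recursions,
and three track summaries are extracted from the result.

**Movement.** A fish diffusing with coefficient $D$ (km²/day) moves between
cells $i \to j$ with probability proportional to
$\exp\!\left(-d_{ij}^2 / (4 D \,\Delta t)\right)$, where $d_{ij}$ is the
great-circle distance between cell centres and $\Delta t = 1$ day. Land
cells are excluded and rows renormalised, which makes the coastline a
reflecting barrier. The kernel support is truncated at
$6\sqrt{2 D \Delta t}$ — six per-axis standard deviations. We deliberately
do not truncate at four: a genuine daily displacement exceeds a $4\sigma$
radius about once per thousand days, so over a 120-day track roughly one
tag in eight would have a *true* path of probability exactly zero, and the
jointly decoded (Viterbi) path is then forced onto a different branch of
the likelihood surface for long stretches. At $6\sigma$ the blocking
probability (~$10^{-8}$/day) is negligible, and since the kernel is stored
dense the wider support costs nothing.

**Observation likelihoods.** Three independent terms are multiplied per day:

* *Bathymetry.* A cell is fully compatible when its charted depth is at
  least the day's maximum tag depth; shallower cells decay as a Gaussian in
  the exceedance with scale `sigma_z` (default 4 m). This is one-sided: a
  fish can always swim above the seabed.
* *Temperature.* The cell's reference temperature interpolates linearly
  between the surface and bottom layers at the day's median depth divided by
  the local bathymetry (clamped to $[0,1]$); the likelihood is Gaussian in
  the difference to the tag's daily mean temperature with scale `sigma_T`.
  Days flagged as cooling-water residence carry no temperature information
  (uniform term) — artificially warmed water matches no cell of any
  realistic reference field — rather than being dropped altogether.
* *Acoustic detections* (when the tag is an acoustic-archival combination).
  On a day with detections, the likelihood at a cell is the maximum over
  detecting stations of $\exp(-\ln 2 \,(d/\sigma_d)^2)$ with
  $\sigma_d = 566$ m, the distance at which the daily detection
  probability is one half; the term is floored at $10^{-6}$. Days without
  detections are uninformative: absence is not used as evidence, because
  detection ranges vary with conditions and receiver coverage is sparse.

The day-one prior is a point mass at the water cell nearest the release
position. A recovery-position anchor is supported but off by default
(`hmm_config(terminal_anchor = )`): tags that wash ashore or drift after
death make the recovery position an unreliable constraint on the last day
at liberty.

**Choice of `sigma_T`.** The default (0.5 °C) is a conservative value on
the order of sensor accuracy plus sub-grid variability, appropriate when
the likelihood is evaluated against a single spot measurement. The term,
however, compares the *daily mean* of ~144 samples with the reference
field, and the sensor-noise contribution to that mean is only
$0.5/\sqrt{144} \approx 0.04$ °C. For the synthetic recovery analyses in
this package we therefore use `sigma_T = 0.15`, which allows for residual
representation error while respecting the averaging; with the
deliberately mis-specified 0.5 the fitted diffusion coefficient attenuates
to roughly half its true value. For real tags, where the reference field's
representation error dominates, larger values are defensible and the
parameter is exposed.

**Degenerate days.** A day whose combined likelihood is zero on every
water cell (conflicting evidence, e.g. an impossible depth) is relaxed to
an uninformative uniform day and counted in a warning, rather than
aborting the fit: long series should not be discarded for single bad days.
The alternative — declaring failure — was rejected.

**Estimation of $D$.** The forward log-likelihood is maximised over $D$ by
golden-section search on the log scale within `D_range` (default
1–100 km²/day) to a 5% relative tolerance. The likelihood is smooth and,
in every profile we have examined, unimodal in $\log D$; a local check
(the returned $D$ beats $D/2$ and $2D$) is part of the test suite.

**Behavioural switching.** Demersal fish alternate between low-activity
(resident) and high-activity (travelling) days, visible in the vertical
activity of the depth series. A two-state Gaussian hidden Markov model on
$\log(1 + \text{activity index})$ — the activity index being the sum of
absolute successive depth differences within a day — is fitted by EM
(≤ 500 iterations, tolerance $10^{-6}$ on the log-likelihood) and decoded
by Viterbi. Switching is engaged only when the fit converges *and* the
state means are at least one pooled standard deviation apart; this
separation screen automates what would otherwise be a visual check of the
state assignment, and a failed screen silently falls back to the single-D
model, which is always a valid special case. With switching on, the
movement kernel of each day is indexed by the previous day's decoded
state, and $(D_\mathrm{low}, D_\mathrm{high})$ are refined by Nelder-Mead
(constrained $D_\mathrm{high} \ge D_\mathrm{low}$) from the single-D fit.
We decode states first and condition the spatial model on them — a joint
cell-by-state HMM would be statistically cleaner but quadruples the state
space, and the two-stage form matches how such analyses are run in
practice.

**Track summaries and reliability.** From the smoothed posteriors we
report the jointly most probable cell sequence (Viterbi; ties toward the
lower cell index), the per-day posterior mode, and the posterior-weighted
mean position. The daily error proxy is the larger of the Viterbi-mean and
Viterbi-mode distances; a track is *reliable* when the median is below
50 km and the maximum below 120 km, usable for temporal-but-not-spatial
interpretation up to a 240 km maximum, and *unreliable* beyond. These
thresholds mirror the error levels reported for demersal and pelagic fish
geolocation, and only reliable/temporal tracks enter the area metrics.

## Preprocessing

* **Depth-sensor drift** is removed by subtracting a centred 7-day running
  minimum (edge windows shrink symmetrically), clamped at zero: a demersal
  fish that surfaces at least weekly should show a near-zero minimum in
  every window, so whatever minimum remains is sensor drift. The window is
  a parameter; 7 days is the default throughout.
* **Mortality.** A dead tag rests on the seabed: the record is truncated at
  the start of a terminal run (≥ 7 days) of daily activity index < 1 m and
  depth range < 0.5 m. `alive_until` is the day before the run starts.
* **Inshore variability.** Sustained (≥ 7 days) diel temperature swings
  above 5 °C at depths under 5 m indicate very shallow inshore water that
  coarse reference fields cannot represent; the series is truncated at the
  onset of the first such episode for geolocation purposes.
* **Cooling-water flags.** A day is flagged when the tag's mean temperature
  exceeds the day's domain-wide maximum water temperature by more than 2 °C
  while the fish stays above 15 m: no natural cell can explain it.
* **Detection QC.** A detection that is its tag's only record on an entire
  receiver array is removed first; then any isolated detection implying an
  out-and-back movement of more than 100 km within a day relative to its
  flanking detections. The singleton rule runs first so that spurious
  singletons cannot anchor the implausibility test.

All four rules are heuristics standing in for judgements that are made
manually (and per tag) in real analyses; every threshold is an exposed
argument, and the flags are carried in the output rather than silently
applied.

## The synthetic data generator

The generator produces the joint structure the analysis assumes, so every
stage is testable without external ocean products:

* **Field.** A 40 × 40 cell domain (0.1° × 0.15°, about the resolution of
  operational north-west European shelf products) with a smooth coastline
  along the eastern edge, depths saturating at 120 m offshore; surface
  temperature = latitudinal gradient (0.8 °C/deg) + seasonal sinusoid
  (±4.5 °C, late-summer peak) + mesoscale anomaly; bottom temperature
  equals the surface in winter and sits up to 3 °C below it in summer over
  deep water. The anomaly is built from two fixed ~200 km-wavelength
  patterns cross-fading over a ~60-day cycle. The temporal evolution
  matters: with a *static* anomaly, cells along a temperature contour stay
  indistinguishable for the whole record and the jointly decoded track can
  lock onto the wrong contour branch; real shelf fields evolve
  synoptically, and so does the synthetic one.
* **Trajectories.** A daily two-dimensional Gaussian random walk with
  per-axis variance $2D(\text{state})\Delta t$, reflected off land, states
  following a sticky two-state Markov chain (defaults $D=5$ and
  30 km²/day — the order of the diffusion coefficients estimated for
  resident vs migrating seabass — with 0.9 persistence).
* **Sensor series.** Ten-minute sampling; a diel depth oscillation between
  the surface and a state-dependent fraction of the local bathymetry (30%
  at low, 90% at high activity, with 1 vs 3 excursions per day), Gaussian
  depth noise; temperature is the two-layer field value at the sampled
  depth plus N(0, 0.5²) noise. Optional linear depth drift, cooling-water
  plumes (fluctuating +ΔT within a radius of a source), and a death day
  after which the tag records an essentially constant seabed depth.
* **Detections and recaptures.** Daily detection probability
  $\exp(-\ln 2 (d/r_{50})^2)$ with $r_{50} = 566$ m — the generator and
  the model share the half-Gaussian curve because only the 50% range is
  known, not the curve's true shape — and a geometric daily recapture
  process with ~1 km position jitter.

What the generator does *not* emulate: tides and advection, 3-D
temperature structure beyond a two-layer column, depth-dependent detection
efficiency, tag shedding, and reference-field bias (the synthetic "truth"
field and the field given to the model are identical, except where drift,
plumes or noise are injected). Passing recovery tests therefore
demonstrates the *estimator* is correct and well-calibrated under the
stated conditions — not that real-tag tracks reach the same accuracy,
which is limited by how well real reference fields represent what a fish
experiences.

## Problem sizes and determinism

The recovery analyses use a 40 × 40 grid (~1,460 water cells), 120-day
tracks and 20 tags; exhaustive-oracle checks of the HMM use up to 10 cells
× 5 days, where full path enumeration is feasible. Every generator draws
from a stream derived deterministically from the master seed, so an
identical configuration reproduces a dataset byte for byte; geolocation
itself is deterministic given its inputs.

## Known limitations

* Area metrics depend on the polygon set supplied; the synthetic area set
  is a latitude-band caricature of the real ICES divisions.
* The migration-strategy rule (most distal area reached for ≥ 5
  known-label days, with the English Channel split east/west at 1° W) is a
  transparent, configurable stand-in for a judgement the original analyses
  made by inspection; the defaults are sensible but not canonical.
* The residency index is a lower bound on presence wherever receiver
  coverage is incomplete — on real arrays it always is.
* `sigma_T` and `sigma_z` are fixed, not estimated; joint estimation with
  $D$ is deliberately out of scope to keep the likelihood profile
  well-behaved on short series.
* The two-stage behavioural switch conditions on a decoded state sequence
  and ignores its uncertainty.
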