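---
title: "Methods: agent-based plankton transport in gridded flow fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agent-based plankton transport in gridded flow fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The transport model

`zoodrift` simulates planktonic organisms as independent point agents in a
steady (optionally time-varying) velocity field sampled on a rectilinear
grid. Per time step `dt`, each active agent's displacement is drawn from a
multivariate normal,

\[
x_{t+\Delta t} = x_t + \varepsilon(x_t), \qquad
\varepsilon \sim N\!\big(v(x_t)\,\Delta t,\; \Sigma\,\Delta t\big),
\]

with `v(x)` the multilinearly interpolated fluid velocity and
\(\Sigma = \mathrm{diag}(\sigma^2_x, \sigma^2_y, \sigma^2_z)\) a diagonal
covariance rate. This is an Euler–Maruyama discretisation of an
advection–diffusion SDE: the organism drifts with the water and swims as an
unbiased random walk. The assumptions it encodes are deliberate
simplifications: agents do not interact, do not alter the flow, carry no
inertia, and have no behavioural bias (no phototaxis, no shear avoidance);
those are the natural next layers, not part of this model.

Units are mm and mm/s throughout the simulation layer (matching how
laboratory-scale flow and swimming speeds are reported); the
dimensionless-number helpers take SI inputs, with `mm_to_m()` /
`mm_s_to_m_s()` converters.

### Parameters that matter

* `variance_rate` (σ², mm²/s, per axis; default 2.5) — the organism's
  effective diffusivity scale. The default corresponds to an effective
  diffusion constant reported for *Artemia* nauplii from video-tracking
  data, halved to spread the measured planar motility over three movement
  axes. It is the single biological control knob: 0 gives passive tracers,
  larger values faster random swimming.
* `dt` (s; default 0.1) — integration and arrival-detection resolution.
  Statistics of interest (medians, modes) are conventionally reported at
  0.1 s granularity, which this default matches; halving `dt` changes
  arrival times by less than the discreteness it removes.
* `n_agents` (default 10,000) — reference campaign size; tests scale this
  down (see below).
* `t_end` (s; default 600) — a safety cap only. With zones registered, a
  run normally ends when every agent has entered all zones or left the
  domain; the cap guarantees termination on pathological fields, and the
  result records which condition fired.
* `u_max` (mm/s; default 44.4) — peak inflow speed of the parabolic channel
  profile, the laboratory tank's operating point.

### Numerical choices

* **Interpolation.** Multilinear (bilinear/trilinear) on the tensor grid;
  grids may be non-uniform (CFD exports usually are). Queries outside the
  grid's bounding box are clamped to the box before interpolating — agents
  projected onto walls then see the wall-adjacent velocity rather than an
  extrapolation artifact. Time-varying fields interpolate linearly between
  snapshots and extrapolate as constants outside the snapshot range.
* **Boundary handling.** The full stochastic displacement is applied first,
  then boundaries once per step: no sub-step reflection. An agent outside
  the box is projected to the nearest boundary point (componentwise clamp —
  exact for an axis-aligned box) if only `project` faces are violated; if
  any violated face is an `exit` face, the agent leaves the simulation.
  Exit dominates projection when both are violated in one step; the exit
  face recorded is the first violated in axis order (x before y before z,
  min before max).
* **RNG discipline.** One seeded generator per run; normal draws are
  consumed in agent-major order (agent 1's x, y, z, then agent 2, ...), and
  inactive agents consume none. Identical configuration + seed therefore
  reproduces trajectories bit-for-bit, and σ² = 0 runs are seed-invariant.
* **Arrival detection.** First entry is recorded at step resolution: the
  first sampled position inside the zone. Within-step excursions across a
  zone boundary are invisible, which biases detected first-passage times
  late by roughly \(0.583\,\sigma\sqrt{\Delta t}\) worth of barrier
  distance (the standard continuity correction for discretely monitored
  crossings); at the default `dt` this is well under the reporting
  granularity, and the test suite accounts for it explicitly when checking
  the inverse-Gaussian first-passage law at small `dt`.
* **Moments.** `moment_stats()` uses population (1/n) central moments:
  skewness \(m_3/m_2^{3/2}\) and non-excess kurtosis \(m_4/m_2^2\)
  (normal → 3). Degenerate samples (\(m_2 = 0\)) report std = skewness =
  kurtosis = 0 by convention, so a passive-tracer run yields an all-zero
  spread row rather than NaNs. The mode of a continuous sample needs a
  binning convention: times are binned into intervals of width `mode_bin`
  (default `dt`) *centred* on multiples of `mode_bin`, the mode is the
  centre of the fullest bin, ties going earliest. Centred bins make a
  constant sample's mode equal the constant, which edge-anchored bins would
  not.
* **Weighted quantiles.** `appearance_boxstats()` summarises an occupancy
  series as a weighted sample of times. Quantiles interpolate the weighted
  empirical CDF at plotting positions \(p_k = (C_k - w_k)/(W - w_n)\),
  chosen because it reduces exactly to R's default (type 7) sample
  quantiles under equal weights.

## The synthetic canopy flow

No reference CFD fields ship with the package, so `canopy_field()`
generates a steady 3D stand-in reproducing the qualitative structure of
flow over a submerged macrophyte bed in a channel:

* a parabolic base profile `u(z) = u_max · 4z(H − z)/H²` (no-slip bottom
  and surface, peak at mid-depth);
* inside the canopy footprint, a multiplicative velocity deficit: a smooth
  (tanh) shear layer rising from `in_canopy_fraction` of the free-stream
  speed deep in the canopy to the free stream above it. The layer is
  centred one `transition_width` *above* the canopy top — the sheltered
  region extends a little above the obstructions rather than stopping at
  them — and the overtopping flow is mildly accelerated (displaced volume
  flux, `overtop_boost`, capped at `speed_cap · u_max`);
* a weak upward component over the leading edge (flow redirected over the
  bed);
* downstream, a wake whose deficit (`wake_deficit` at the trailing edge,
  confined below the shear layer) recovers linearly over `wake_length`.

Stem-scale geometry is deliberately not resolved: the agent model only ever
consumes the velocity field, and the bulk effects that drive arrival-time
differences are the in-canopy slow-down and the sheltered wake. Density is
therefore abstracted into `in_canopy_fraction`; `scenario_suite()` maps the
three reference stem grids to fractions 0.5 (8×15), 0.3 (10×20) and 0.05
(15×30) — a tunable ordering choice, not a measurement — and deepens the
wake deficit with density (`wake_deficit = 1 − fraction`), since a denser
bed blocks more flow and sheds a more strongly sheltered wake. The
streamwise taper of flow through successive stem rows is not modelled (the
deficit is uniform along the footprint); no incompressibility correction is
applied, matching the practice of advecting agents directly on a raw
gridded field.

What passing the fixture-based tests shows, and what it does not: the suite
demonstrates that the simulator converts slow sheltered regions into
longer, more dispersed arrival times, ordered by density, with every canopy
slower than the no-canopy plate control. It does not validate any
quantitative arrival table against a real bed geometry — that requires the
actual CFD or measured field for that geometry, which is exactly what the
`read_grid_field()` importers are for.

## Design decisions taken where the design was open

* **Release point.** "Directly upstream of the bed, near the bottom" is
  implemented as 1 mm upstream of the canopy's upstream face, on the tank
  centreline, 3 mm above the bottom (configurable). An alternative reading
  places the release inside or downstream of the bed's centre; upstream
  release is the one consistent with injecting organisms ahead of the
  structure and letting the bed act on them.
* **Zone geometry.** Zones constrain streamwise position and height
  (default 40 mm wide × 80 mm tall, eight 20 mm cells) and span the full
  tank width, since zone observation integrates across the tank's line of
  sight. The green zone abuts the canopy's trailing edge; the blue zone
  sits 150 mm further downstream.
* **Exit bookkeeping.** Agents that leave downstream before entering a zone
  are recorded as non-arrivals and excluded from that zone's moments (they
  cannot re-enter; tracking stops at exit).
* **Sweep seeding.** Scenario *i* of a sweep runs with `seed + i − 1`, so
  serial and parallel execution produce identical artifact sets.
* **Tiling.** Periodic expansion requires the first and last transverse
  slices of the tiled axis to agree (they represent the same physical plane
  one period apart); the duplicated plane is dropped when concatenating, so
  tiled fields are exactly periodic at and between nodes. The check can be
  disabled for almost-periodic fields.

## Problem sizes used by the shipped tests

The test suite runs the reference physics at reduced scale, chosen as the
smallest sizes at which each statistical check is sharp: Brownian variance
and inverse-Gaussian first-passage at 4,000–10,000 agents (`dt` 0.01 s for
the first-passage law, so discreteness is far below the distribution's
spread); the canopy trend suite at 2,000 agents × 3 seeds per scenario,
averaging seed means before comparing; the diffusivity probe at 500 agents
across the ten reference variance rates. The campaign defaults remain at
10,000 agents.

## Known limitations

* Steady fields are first-class; the time-varying path is implemented and
  tested but has no file-format support (build snapshot sequences in code).
* The synthetic canopy is divergence-agnostic: interpolated velocities near
  strong deficit gradients do not conserve mass, so streamline-level
  quantities (not used by the agent model) are not meaningful there.
* Arrival detection at step resolution slightly inflates first-passage
  times at coarse `dt`; reduce `dt` where absolute arrival values matter.
* A single variance rate describes swimming; ontogenetic or
  behaviour-dependent motility needs per-agent rates, which the state
  layout would admit but the update rule does not currently expose.
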