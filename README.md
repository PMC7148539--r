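# zoodrift

Agent-based simulation of zooplankton transport through complex flow fields.

Weakly swimming planktonic larvae — brine shrimp (*Artemia*) nauplii are the
motivating organism — disperse through vegetated habitats as a combination of
passive advection by the local flow and their own effectively diffusive
swimming. `zoodrift` simulates this at the individual level: thousands of
agents ride a gridded velocity field (a CFD export, a measured field, or a
built-in synthetic macrophyte-canopy flow) while performing an unbiased
Gaussian random walk, and the package records when each agent first reaches
downstream observation zones. The question the machinery answers is
ecological: how much does a submerged canopy of given density and height
delay and spread the arrival of drifting larvae downstream?

## The model

Each agent's position `x` is updated per time step `Δt` by

```
x(t + Δt) = x(t) + ε(x),    ε ~ N( v(x) Δt,  Σ Δt )
```

where `v(x)` is the fluid velocity at the agent, obtained by multilinear
(bilinear/trilinear) interpolation of a rectilinear-grid velocity field, and
`Σ = diag(σ²)` holds a per-axis diffusive variance rate (mm²/s) describing
the organism's random swimming (default `σ² = 2.5 mm²/s`, an effective
diffusivity measured for *Artemia* nauplii). Domain faces are tagged
per-face: agents crossing a wall, the bottom or the fluid surface are
projected back to the nearest boundary point; agents crossing the open
upstream or downstream face leave the simulation. With constant drift `u`
and variance rate `σ²`, first-passage times to a plane at distance `L`
follow an inverse-Gaussian law with mean `L/u` and shape `L²/σ²` — the
closed form the test suite uses as an oracle.

Arrival-time samples are summarised the way such tables are conventionally
reported: mean, median, binned mode, population standard deviation, and
Pearson standardised moments (skewness `m₃/m₂^{3/2}`, non-excess kurtosis
`m₄/m₂²`).

Supporting tooling includes VTK (legacy ASCII rectilinear-grid) and
delimited field file I/O, periodic flow tiling, an analytical parabolic
channel profile, a synthetic canopy-flow generator with slow in-canopy flow,
accelerated overtopping flow and a recovering wake, zone occupancy time
series, Reynolds-number and velocity-ratio helpers, and a config-driven
campaign runner with density and diffusivity sweeps
(`inst/cli/zoodrift.R` is a thin command-line wrapper).

## Worked example

Simulate 2,000 nauplii released 1 mm upstream of a 2 cm-tall canopy of
intermediate density in a 320 mm flow tank, and summarise their arrivals in
the two downstream camera zones:

```r
library(zoodrift)

tank  <- default_tank()                       # 80 x 320 x 80 mm working section
bed   <- canopy_spec(canopy_height = 20, in_canopy_fraction = 0.3)
flow  <- canopy_field(bed, u_max = 44.4, domain = tank)
zones <- default_zones(bed, tank)             # green + blue observation zones
cfg   <- sim_config(release_point = c(59, 40, 3), n_agents = 2000,
                    variance_rate = 2.5, dt = 0.1)

run <- simulate_swarm(cfg, flow, tank, zones, seed = 42)
run
#> <swarm_sim> 2000 agents, 1386 steps (138.6 s), terminated: all_done
#>   zone 'green': 2000/2000 arrived
#>   zone 'blue': 2000/2000 arrived
#>   exited domain: 1999  still active: 1
summary(run)
#>   label    n    Mean Median Mode      Std Skewness Kurtosis
#> 1 green 2000 23.2952  20.85 13.9 10.31495 1.059658 4.143948
#> 2  blue 2000 41.4864  37.30 28.0 17.50181 0.966919 3.649404
```

Every agent reached the green zone (mean first arrival 23.3 s, right-skewed:
a fast advected bulk plus a sheltered tail) and the farther blue zone
(mean 41.5 s, wider spread); nearly all then exited downstream. For the same
flow, the dimensionless regime numbers:

```r
reynolds(fluid_params(U = 0.0444, L = 0.0025))   # stem-scale Re
#> [1] 105.3472
velocity_ratio(1, 44.4)                          # swimming vs peak flow
#> [1] 0.02252252
```

`sweep_density()` repeats such runs over a suite of canopy heights and
densities plus a no-canopy plate control, and `sweep_diffusivity()` over a
grid of variance rates; both write one summary-statistics row per scenario.

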