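Package: zoodrift
Title: Agent-Based Simulation of Zooplankton Transport in Gridded Flow Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lagrangian agent-based simulation of planktonic organisms (e.g.
    Artemia nauplii) advected by steady or time-varying rectilinear-grid
    velocity fields while performing an unbiased Gaussian random walk.
    Provides multilinear velocity interpolation, periodic flow tiling,
    analytical channel and synthetic macrophyte-canopy flow fields, per-face
    domain boundary conditions (projection onto walls, exit at open faces),
    zone-based first-arrival recording, occupancy time series, and
    Pearson-moment arrival-time statistics, together with a configuration
    driven campaign runner for density and diffusivity sweeps.
License: MIT
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
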