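Package: pointdiff
Title: Pointwise Diffusion-Property Inference for Single-Particle Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterize heterogeneous diffusion from
    single-particle-tracking trajectories at single-time-step resolution.
    Provides exact simulators for the standard anomalous-diffusion models
    (piecewise Brownian motion, fractional Brownian motion, scaled Brownian
    motion, continuous-time random walks, Levy walks and the annealed
    transient-time model), a sequence-to-sequence neural regressor that
    predicts the diffusion coefficient or the anomalous exponent at every
    time step, classical time-averaged mean-squared-displacement baselines,
    kernel changepoint detection for segmenting trajectories into diffusive
    states, benchmark metrics (relative error, absolute error, Jaccard index
    for changepoints), and segment-level analysis operators (power-law tail
    fits, dwell-time coupling, diffusive-state clustering, turning angles,
    confinement radii).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
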