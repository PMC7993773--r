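Package: srpdyn
Title: Linear-Nonlinear Models of Short-Term Synaptic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and maximum-likelihood inference for the Spike
    Response Plasticity (SRP) model of short-term synaptic dynamics, a
    linear-nonlinear cascade in which a causal efficacy kernel is convolved
    with a presynaptic spike train and passed through a sigmoidal readout to
    set the mean of gamma-distributed postsynaptic amplitudes, with a second
    kernel controlling their dynamic standard deviation. Includes the classic
    and extended Tsodyks-Markram models as benchmarks, stimulation-protocol
    and Poisson spike-train generators, surrogate amplitude-table synthesis,
    gamma negative log-likelihood fitting with multistart L-BFGS-B, grid
    search for Tsodyks-Markram parameters, and evaluation tools
    (per-pulse statistics, noise correlations, parameter-recovery curves,
    protocol hold-out with bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
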