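Package: dwssfp
Title: Protocol Optimization and Simulation for Diffusion Imaging of
    Post-Mortem Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative comparison of diffusion-weighted spin echo (DW-SE)
    and diffusion-weighted steady-state free precession (DW-SSFP) for
    post-mortem (fixed-tissue) brain MRI. Implements exact steady-state
    signal models for pulsed-gradient SSFP via a configuration-state
    (extended phase graph) formulation, the effective b-value that maps
    DW-SSFP diffusion contrast onto an equivalent spin-echo b-value,
    SNR-efficiency optimization of sequence protocols under timing and
    gradient constraints, and a synthetic-voxel simulator with a Bayesian
    (MCMC) ball-and-stick fitter that quantifies fiber-orientation
    uncertainty for both sequences at matched scan time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
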