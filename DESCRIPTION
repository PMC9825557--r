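Package: amygaze
Title: Saccadic Orienting Under Transient Amygdala Disruption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of two-alternative saccadic orienting
    experiments with transient unilateral amygdala disruption. Provides a
    synthetic-experiment generator with known ground truth (trial design,
    drift-diffusion behaviour, eye traces, local field potential epochs and
    face difference images), saccade detection with reaction-time quality
    control, a Wiener first-passage-time likelihood core, hierarchical
    Bayesian models of latency (shifted lognormal), choice (Bernoulli) and
    joint choice/latency (drift-diffusion) with planned posterior contrasts,
    pixelwise fixed-effects inference on face difference images, and induced
    time-frequency analysis of intracranial local field potentials, both with
    permutation-based family-wise error control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    png
Config/testthat/edition: 3
NeedsCompilation: yes
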