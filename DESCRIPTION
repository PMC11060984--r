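Package: mrpinn
Title: Multi-Resolution Physics-Informed Recurrent Networks for
    Musculoskeletal Parameter Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simultaneous surface-EMG-driven joint motion prediction and
    Hill-type muscle parameter identification with physics-informed
    recurrent neural networks trained coarse-to-fine on a wavelet
    multi-resolution ladder.  Includes a rigid-tendon Hill-type elbow
    flexion-extension forward-dynamics simulator, a Daubechies-2
    multi-resolution signal decomposition, gated recurrent units with
    teacher forcing and autoregressive rollout, a composite loss
    combining data misfit with the equation-of-motion residual, a
    sequential coarse-to-fine trainer with weight transfer, a synthetic
    verification-data generator, and command-line entry points for the
    full experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
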