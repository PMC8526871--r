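Package: spfm
Title: Stochastic Hierarchical Bayesian Modelling of Functional Brain Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian matrix factorisation of multi-subject
    resting-state fMRI into probabilistic functional modes: subject- and
    group-level spatial maps with a double-Gaussian signal/noise mixture,
    HRF-constrained mode timecourses with hierarchically Wishart-coupled
    precision matrices, positive mode amplitudes, and Gaussian residual
    noise. The model is fitted with stochastic variational Bayes so that
    populations far larger than memory can be analysed: the group model is
    updated from weighted random subject batches with a decreasing step
    size and a final alignment pass over all subjects. Ships with a
    calibrated multi-subject fMRI simulator with known ground truth, an
    incremental group-PCA (MIGP) spatial basis, a deterministic spatial-ICA
    initialiser, an ICA plus dual-regression baseline with Tikhonov partial
    correlation network matrices, and mode-pairing evaluation machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    RNifti,
    jsonlite,
    tibble,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
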