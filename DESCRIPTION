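Package: rtscr
Title: Random-Thinning Spatial Capture-Recapture for Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian spatial capture-recapture (SCR) analysis of camera-trap
    surveys in which part of the photographic detections cannot be assigned to
    an individual.  Implements the random-thinning SCR model (rt-SCR), where
    every encounter retains its individual identity with probability theta and
    unidentified encounters are observed only as trap-level count sums.
    Provides a forward simulator of the full generative process, a
    Metropolis-within-Gibbs sampler with data augmentation and exact
    multinomial allocation of the latent unidentified counts, posterior
    predictive goodness-of-fit checks, and derived ecological summaries
    (density, abundance, home-range area, closure test, movement distances).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
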