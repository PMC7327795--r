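Package: moveloc
Title: Movement-Assisted Localization for Acoustic Telemetry Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical localization of acoustic transmitters from
    detection/non-detection data recorded at fixed receiver arrays.
    Implements a hierarchical spatial capture-recapture model that joins a
    distance-dependent detection function, a Brownian-motion movement
    process linking successive signal locations, and a signal-rate
    sub-model for random transmission schedules.  Models are fitted by
    custom Metropolis-within-Gibbs samplers, including a trans-dimensional
    sampler that estimates the number of signals missed between successive
    detections.  Ships a simulator for receiver-array studies and the
    evaluation metrics (relative bias, localization RMSE, posterior
    precision, highest-posterior-density coverage) used to benchmark
    localization methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
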