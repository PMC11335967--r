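Package: reverbdecode
Title: Reverberant Impulse-Response Synthesis and EEG Decoding of Acoustic Realism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how listeners and their brains distinguish real
    from synthetic reverberation. Implements cochlear-subband analysis and
    parametric resynthesis of room impulse responses (exponential, linear,
    time-reversed, spectrally flattened and spectrally inverted decay
    variants), construction of RMS-equated convolved stimulus sets with
    balanced block schedules, simulation of multichannel EEG epochs and
    behavioral reports with controllable condition effects, a retrospective
    sliding-window multivariate decoding pipeline (linear support-vector
    classification over pseudo-trial subaverages, temporal generalization,
    sensor-cluster subsetting), and nonparametric group inference
    (cluster-size permutation tests, Spearman brain-behavior correlation,
    Wilcoxon signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
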