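Package: waversa
Title: Time-Resolved EEG Representational Similarity of Overlapping Episodic Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoding-phase EEG analysis pipeline for detecting integrated and
    separated neural representations of overlapping episodic events. Implements
    Morlet wavelet time-frequency decomposition, wavelet-coherence feature
    selection with cluster-based permutation statistics, time-resolved
    representational similarity analysis of time-frequency patterns with dual
    baselines, conjugate Normal-Inverse-Gamma evidence accumulation with
    Savage-Dickey Bayes factors and supra-threshold window detection, trial-level
    Bayesian linear regression linking neural (dis)similarity to associative and
    source memory, and a univariate spectral-power contrast. A synthetic-EEG
    generator emulating the associative-inference movie paradigm makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
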