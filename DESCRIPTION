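Package: squigglesim
Title: Transformer-Based Simulation of Nanopore Sequencing Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates raw nanopore sequencing current signals ("squiggles")
    from DNA sequences with a non-autoregressive feed-forward transformer
    that is trained end-to-end on segmented signal data (eventalign-style
    tables). Includes learned event-duration (gamma) and amplitude-noise
    (Gaussian) samplers, genome- and read-mode simulation with configurable
    read-length distributions, ASCII SLOW5 export, a synthetic ground-truth
    data generator for end-to-end testing and parameter-recovery studies,
    and dynamic-time-warping signal comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    yaml,
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
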