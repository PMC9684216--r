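Package: vtnet
Title: Two-Hemisphere Visuo-Tactile Network Simulation of Bimanual Touch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Firing-rate simulation of a two-hemisphere visuo-tactile neural
    network for bimanual tactile detection. Each simulated hemisphere holds
    topographic tactile and visual hand maps with Mexican-hat lateral
    connectivity, a pooling multisensory unit, and an inhibitory interneuron
    driven, with a callosal delay, by the opposite hemisphere's multisensory
    activity. The package simulates four-alternative forced-choice (4AFC)
    tactile detection with unimanual, bimanual and catch trials, optionally
    paired with task-irrelevant bright/dim visual cues; runs subject cohorts
    with synaptic jitter and stimulus noise; encodes crossmodal-exposure
    plasticity hypotheses as static weight-scaling presets; and computes the
    lateralization bias index (LBI), baseline-corrected response rates, and
    mean-squared-error fits against user-supplied behavioral reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
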