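Package: asrtnet
Title: Statistical Learning Scores and Small-World EEG Coherence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse probabilistic sequence learning in the cued
    Alternating Serial Reaction Time (ASRT) task together with the
    graph-theoretical architecture of EEG functional connectivity.
    The package scores trial-level ASRT logs into statistical-learning
    measures (triplet categorization, trill/repetition exclusions,
    five-block units), estimates band-averaged imaginary coherency from
    multichannel recordings with multitaper cross-spectra, thresholds
    coherence into binary electrode graphs at a percentile cut-off, and
    computes the small-world coefficient omega against random and
    ring-lattice null ensembles. Mixed-design ANOVAs with partial eta
    squared, post hoc contrasts, severity correlations and a
    medication-free sensitivity rerun cover the group-level analyses.
    A synthetic-data generator plants known learning effects and
    phase-lagged connectivity graphs so that every stage of the pipeline
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
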