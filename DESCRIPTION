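Package: wmload
Title: Working-Memory Load Effects and Divisive Normalization in Spike Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for load-resolved information in single-neuron
    spike recordings from a delayed change-localization working-memory task.
    Computes omega-squared percent-explained-variance (PEV) timecourses for
    color identity at a neuron's favorite location, permutation-based
    significance and neuron classification across memory loads, population
    load-effect statistics with error-trial subsampling, hierarchical
    clustering of information timecourses, and the divisive-normalization
    selectivity/sensory-interaction (SE/SI) index regression.  Includes a
    synthetic-data generator that emulates the task (six locations, two
    colors per location, array sizes two to five, 800 ms sample, 1000 ms
    delay) with Poisson spiking under weighted divisive normalization, so
    the whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
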