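Package: spikepatterns
Title: Spike-Time Pattern and Event Analysis at Neuronal Bifurcation Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how noisy conductance-based neurons respond to
    repeated ("frozen noise") current injections. Simulates the Wang-Buzsaki
    single-compartment neuron with per-trial noise and an optional slow
    potassium current, generates frozen-noise and frequency-modulated stimuli,
    and analyses the resulting spike-train ensembles: Schreiber R-reliability,
    Victor-Purpura spike-train distances, fuzzy c-means pattern clustering with
    gap-statistic model selection, interval-method event detection with
    ROC-based merging of events shared between patterns, entropy and mutual
    information of pattern distributions with resampling bias estimates, and
    event-based stimulus reconstruction from the spike-triggered average.
    Amplitude and offset sweeps locate bifurcation points where spike patterns
    multiply and reliability dips.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    graphics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
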