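Package: stripedyn
Title: Dynamics of an Incoherent Feedforward Loop in Terminal Embryo Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and quantifies the dynamical interpretation of ERK
    signalling by the tailless/huckebein/brachyenteron incoherent feedforward
    loop of the early Drosophila embryo. Provides optogenetic stimulus
    scenarios over the nuclear-cycle schedule, a cumulative-dose circuit model
    in which repressor onset is delayed in proportion to one over the ERK
    amplitude, a one-dimensional reaction-diffusion extension that converts an
    all-or-none light boundary into a graded response and a stripe of
    sustained output transcription, a synthetic two-channel movie renderer
    with ground-truth burst tables, and an MS2 burst-quantification pipeline
    (focus detection, bursting-state annotation, proportion-bursting curves,
    the time-to-50-percent statistic, quantification-box placement and
    membrane-enrichment profiles). All analyses run on synthetic data with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
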