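Package: syllastream
Title: Constrained Syllable-Stream Design and ERP Analysis for Auditory
    Statistical-Learning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building artificial-language statistical-learning
    experiments and analysing them end to end. Constructs trisyllabic
    high- and low-transitional-probability lexicons with zero-probability
    foils, generates constrained pseudo-random familiarization streams
    with a chirp cover task and a millisecond event timeline, simulates
    two-alternative forced-choice behaviour and continuous multichannel
    EEG with condition-dependent N100/N400 components, runs the ERP
    pipeline (mastoid re-reference, zero-phase Butterworth band-pass,
    epoching, baseline correction, threshold artifact rejection, region
    of interest amplitude extraction), and fits the behavioural and ERP
    statistics (one-sample t-tests against chance, mixed and repeated
    measures ANOVA with Greenhouse-Geisser correction, Bonferroni
    pairwise adjustment, partial eta squared, observed power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
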