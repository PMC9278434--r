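Package: sleepbreathr
Title: Sleep-Apnoea Phenotyping from Plethysmography, EEG/EMG and Maze Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping sleep-disordered breathing in rodents from
    whole-body plethysmograph airflow together with EEG/EMG sleep staging.
    Segments airflow into breaths and computes tidal volume, respiratory
    frequency and minute ventilation; stages 5-second epochs into
    WAKE/NREM/REM/DOUBT from delta and theta band power and EMG tone; detects
    apnoeas and hypopnoeas as sustained reductions in minute ventilation and
    summarises the apnoea-hypopnoea index per hour of sleep by state; scores
    Barnes-maze search strategies and Y-maze novelty preference from tracked
    trajectories; and provides normality-gated group comparisons with a robust
    15th-85th percentile spread statistic. A synthetic-recording generator with
    known ground truth (scripted hypnograms, injected ventilation-reduction
    events, state-dependent EEG/EMG) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
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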