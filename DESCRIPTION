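Package: screenqaly
Title: Benefit-Harm Modelling of Organized Mammographic Screening in Net QALYs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic cohort model of the benefits and harms of organized
    biennial mammographic screening, expressed in quality-adjusted life years
    (QALYs). Two hypothetical cohorts of women are projected from age 50 under
    competing breast-cancer and other-cause mortality; screening benefit enters
    as an age-shaped proportional reduction in breast-cancer mortality and is
    converted to life-years gained with a mortality-transfer factor, while
    harms accrue from false-positive screening results and from treatment of
    overdiagnosed cancers. Net QALYs, cumulative trajectories, turning ages and
    tornado sensitivity analyses are produced for configurable scenarios. A
    synthetic generator of BreastScreen-Norway-like individual screening
    histories provides a stochastic micro-simulation oracle and re-derives all
    data-driven model inputs (cumulative false-positive risk, detection-mode
    mixes, treatment distributions) without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
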