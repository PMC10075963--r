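Package: bilexread
Title: Bilingual Reading Stimulus Statistics, Miniblock Schedules, and
    ROI-Level fMRI Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the reading network of bilinguals
    responds to letter strings that increasingly resemble real words.
    Builds bilingual orthographic-statistics stimulus sets (letter, bigram
    and quadrigram frequency tables from word-frequency lexica; a
    14-condition design crossing per-language component frequencies with
    matched real-word categories), constructs miniblock fMRI run schedules
    with jittered fixations and catch trials, and implements ROI-level
    statistical analyses: word-similarity regression slopes with
    false-discovery-rate control, posterior-to-anterior spatial gradients
    in Talairach coordinates, selectivity and language-dominance indices,
    a general linear model with two-gamma haemodynamic response and AR(2)
    serial-correlation correction, a battery of condition contrasts, and a
    nonparametric independent component decomposition of voxel response
    profiles. A synthetic-data module generates bilingual lexica and ROI
    cohorts with planted effects so the full pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
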