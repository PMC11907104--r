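Package: microstatr
Title: Resting-State EEG Microstate Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for resting-state EEG microstate analysis:
    average re-referencing, 2-20 Hz zero-phase band-pass filtering, global
    field power (GFP) computation and peak detection, polarity-invariant
    atomize-and-agglomerate hierarchical clustering (AAHC) of GFP-peak
    topographies, hierarchical template sorting and backfitting
    (grand grand mean to group grand means to individual template sets),
    quantification of microstate duration, occurrence, coverage, mean GFP,
    global explained variance and transition syntax, and the accompanying
    group statistics (mixed ANOVA with Greenhouse-Geisser correction, Welch
    t tests with Bonferroni correction over transition pairs, Cohen's d,
    and a randomization TANOVA on normalized topographies).  Includes a
    semi-Markov synthetic EEG cohort generator with known microstate ground
    truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
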