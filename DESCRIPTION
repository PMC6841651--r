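Package: phrex
Title: Phase-Type Stroke Recovery Models for Hospital Length of Stay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and interrogates a four-phase continuous-time Markov
    (phase-type) model of in-patient stroke recovery with three absorbing
    discharge modes (death, nursing home, usual residence) and age-linked
    transition intensities. Provides the closed-form per-patient likelihood,
    a staged backward maximum-likelihood estimation procedure with
    observed-information standard errors and rate pruning, key performance
    indicators (destination probabilities, overall and destination-conditional
    mean length of stay, mean residual stay, stay-conditional destination
    probabilities), a seeded synthetic-cohort simulator, and goodness-of-fit
    diagnostics comparing Nelson-Aalen cause-specific cumulative intensities
    with their model counterparts by age band.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), survival, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
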