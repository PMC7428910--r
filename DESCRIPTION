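Package: elmh
Title: Four-Quadrant Mental-Illness Screening with Rasch Person Fit and a
    Micro Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies respondents of a 44-item, 8-domain workplace
    mental-health questionnaire into four classes (mental illness, health,
    and their low-confidence "false" counterparts) by crossing a
    continuous-response Rasch person measure with the outfit mean-square
    person-fit statistic. Provides exploratory factor scoring with Bartlett
    weights and per-domain regression shortcuts, joint maximum-likelihood
    Rasch estimation with rating-scale category-probability curves, a
    108-parameter per-class convolutional network trained by full-batch
    gradient descent to reproduce the quadrant labels from raw responses, a
    linear discriminant baseline, survey sample-size planning with finite
    population correction, and a seeded cohort simulator with known latent
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
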