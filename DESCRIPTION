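Package: devtoxrank
Title: Combined Placental-Transfer and Stem-Cell Differentiation Screening
    for Developmental Toxicity Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to predict relative in vivo developmental toxicity of
    chemicals from two in vitro assays. Transwell (BeWo b30) transport time
    courses are converted into apparent permeability (Papp) coefficients
    with an explicit correction for periodic sampling with buffer
    replacement, and expressed relative to a freely transported reference
    compound. Embryonic stem cell (ES-D3) embryoid-body differentiation
    counts are fitted with the standard suite of eight dichotomous
    concentration-response models by binomial maximum likelihood to derive
    a benchmark concentration for 50 percent loss of differentiation
    (BMC50), taken as the lowest estimate among models passing
    goodness-of-fit screening. Dividing BMC50 by relative Papp yields a
    transfer-corrected potency used to rank compounds, and rank concordance
    with an external in vivo ordering is quantified. A seeded synthetic-data
    generator emulates both assays with known ground truth so every
    pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
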