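Package: lineup2ht
Title: Two-High-Threshold Multinomial Modeling of Eyewitness Lineup Identification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained maximum-likelihood estimation of the two-high-threshold
    (2-HT) eyewitness identification model, a multinomial processing tree model
    that decomposes lineup responses (suspect selection, filler selection,
    rejection) into latent detection and non-detection processes: culprit-presence
    detection (dP), culprit-absence detection (dA), biased suspect selection (b)
    and guessing-based selection (g). Provides multi-condition model building with
    equality constraints and fixed constants, G-squared goodness of fit,
    likelihood-ratio (delta G-squared) tests of nested parameter hypotheses,
    observed-information standard errors, noncentral chi-square sensitivity/power
    analysis (Cohen's w), a multinomial simulator for parameter-recovery studies,
    and turnkey reproduction of two lineup-presentation-format experiments from
    their published response-frequency tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
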