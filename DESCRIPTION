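Package: silkqtl
Title: QTL Mapping for Achiasmate F2 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composite-interval QTL mapping for F2 populations of species with
    achiasmate female meiosis, such as the silkworm (Bombyx mori). Provides
    conditional QTL-genotype probabilities that respect the absence of
    crossing-over in female gametogenesis, mixed-linear-model genome scans for
    main and digenic epistatic QTL effects with QTL-by-sex interactions,
    permutation-based significance thresholds, Gibbs-sampling estimation of
    genetic effects, an F2 population simulator for both achiasmate and
    chiasmate designs, and tools to quantify the coefficient bias incurred by
    applying the standard chiasmate F2 model to achiasmate data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
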