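Package: herbivoc
Title: Herbivory-Induced Plant Volatile Emission Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for herbivory-induced biogenic volatile
    organic compound (BVOC) emissions measured by branch-enclosure
    sampling and GC-MS. Covers blank subtraction and compound filtering
    of adsorbent-cartridge peak tables, proxy-standard quantification,
    leaf-area-normalised emission-rate calculation, randomized-block
    mixed-model treatment statistics with Tukey contrasts, damage
    dose-response regressions, blend-composition analysis (proportions,
    PCA, random-forest discrimination), and phenotypic-integration and
    connectance metrics of compound correlation networks. Includes a
    synthetic-data generator emulating larval-density manipulation
    experiments for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nlme,
    multcomp,
    randomForest,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
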