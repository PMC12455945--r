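Package: urotag
Title: Restriction-Tag Urobiome Profiling and Postoperative SIRS Risk Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species-level microbiome profiling from type-IIB restriction
    enzyme tags (2bRAD-style) together with the downstream statistics used
    to relate a low-biomass urobiome to a binary clinical outcome. Builds a
    species-unique marker database by in-silico digestion of reference
    genomes, assigns reads to species with a G-score false-positive filter
    and marker-normalized relative abundances, screens negative-control
    contaminants, computes alpha/beta diversity with PERMANOVA and PCoA,
    identifies differential taxa by rank tests, LDA effect sizes, linear
    models and indicator-species analysis, and combines random-forest
    selected microbial biomarkers with clinical covariates in logistic
    prediction models evaluated by ROC/AUC. Includes a synthetic-data
    generator for genomes, reads, two-group communities and clinical
    covariates so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vegan,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
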