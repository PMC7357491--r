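Package: rhizorank
Title: Multicriteria Selection of Plant Growth-Promoting Rhizobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies plant growth-promoting rhizobacteria (PGPR) phenotype
    assays (phosphate solubilization halos, siderophore capture, motility,
    reactive-oxygen-species sensitivity, biofilm formation, Biolog Eco-plate
    carbon-source kinetics) into per-strain performance values via linear and
    random-intercept mixed models with Tukey pairwise letters; converts the
    performance values to 0-1 utility scores with exponential single-attribute
    value functions elicited from min/mid/max anchors; aggregates the scores
    under criterion-weight scenarios (plant growth, colonization, persistence);
    and ranks candidate strains. Ships a calibrated synthetic-assay generator
    so the whole pipeline is testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    emmeans,
    withr
Config/testthat/edition: 3
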