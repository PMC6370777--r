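Package: graftmicrobe
Title: Leaf Microbiome Analysis of Grafted Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for amplicon (OTU-table) surveys of leaf
    microbiomes in grafted-plant field experiments. Provides the
    preprocessing cascade used in such studies (per-sample low-abundance
    cell filtering, rarefaction without replacement, taxonomic collapsing,
    occurrence filtering), community-level tests (Raup-Crick null-model
    beta-diversity, PERMANOVA, per-taxon ANOVA, rarefaction and
    species-accumulation curves), and a randomization-based host-genotype
    preference index with permutation null and Bonferroni correction.
    Includes a Dirichlet-multinomial synthetic-data generator emulating a
    9-rootstock x 15-replicate-set tomato field design for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    vegan,
    biomformat,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
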