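Package: mindep
Title: Metabolic Independence, Module Completeness and Colonization
    Phenotypes from Genome-Resolved Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify the metabolic independence of gut microbial
    genomes and to relate it to colonization outcomes after fecal microbiota
    transplantation (FMT). Parses KEGG-style module definitions, computes
    per-genome pathwise module completeness from KEGG Ortholog annotations,
    derives read-recruitment detection and coverage summaries, assigns
    colonization phenotypes to genome/recipient pairs using strain-level
    subpopulation evidence, tests modules for group enrichment with a
    binomial-GLM Rao score statistic and Benjamini-Hochberg FDR, and scores
    genomes as having high or low metabolic independence over an enriched
    module set. A deterministic synthetic-data generator emulates the
    statistical structure of FMT cohort metagenomes so every stage can be
    tested without external data.
License: MIT
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
    withr,
    optparse
Config/testthat/edition: 3
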