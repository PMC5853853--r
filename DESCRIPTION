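Package: elicitR
Title: Genetic Dissection of Elicitor-Responsive Transcriptional Programs
Version: 1.0.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for dissecting pathogen-associated molecular
    pattern (PAMP) induced transcriptional responses in a wild type /
    phosphatase mutant / phosphatase-kinase double mutant design. Provides
    per-timepoint classification of elicitor-responsive transcripts into
    MKP1/MPK6 pathway-dependency categories, short time-series model-profile
    clustering with archetype grouping, singular enrichment analysis via
    Fisher's exact test with Benjamini-Hochberg FDR control, and
    efficiency-corrected qPCR quantification from amplification curves.
    A synthetic-data module generates every pipeline input with known ground
    truth so each stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
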