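Package: cnvdosage
Title: Population-Level CNV Dosage Calling and Multivariate Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for population-level copy-number variant (CNV)
    analysis from SNP-array intensities. Implements GC and genomic-wave
    correction of Log-R ratios, a population-shared-emission hidden Markov
    model for copy-number calling with EM fitting and multi-cohort joint
    calling, expected CNV genotypes ("countAll" dosages) with certainty
    filtering and CNV allele frequencies, univariate and reverse-regression
    (joint) multivariate association models with backward variable
    selection, an effective-number-of-tests Sidak correction, cis CNV-eQTL
    scans with reciprocal-pair detection, consensus non-negative matrix
    factorization gene programs, and region-level bisulfite methylation
    summaries with a periodic "methylation wave" score. A synthetic-cohort
    generator with known CNV haplotypes, intensity artefacts, phenotypes,
    cis-regulated expression and methylation tracks makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
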