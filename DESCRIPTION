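Package: afreclass
Title: Ancestry-Aware Reassessment of Reported Pathogenic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for re-evaluating reported pathogenic variants of
    rare monogenic diseases against multi-ancestry population allele
    frequencies. Merges variant registries from multiple source databases,
    annotates per-population allele frequencies from tabular or VCF
    resources, computes a disease-specific maximum credible allele
    frequency from prevalence, allelic contribution and penetrance, flags
    variants whose frequency in any ancestry meets an applied cutoff,
    determines ancestry restriction of flagged variants, maps ion-channel
    residues to topological domains, and compares flagging rates between
    strata with exact and chi-square tests. Ships a worked Brugada
    syndrome (BrS) dataset and a seeded synthetic-data generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
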