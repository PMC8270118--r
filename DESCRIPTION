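Package: newgeness
Title: Essentiality Analysis of Evolutionarily New Genes from RNAi Screens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to ask whether evolutionarily young genes are essential,
    built around Drosophila RNAi knockdown screens. Implements phylogenetic
    gene-age dating by Dollo (single-gain) parsimony on species
    presence/absence patterns, lethality phenotype calling from F1 progeny
    counts, landing-site genotype filtering for KK-library artifacts,
    between-screen concordance summaries, knockdown-efficiency
    quantification from qPCR Ct tables by the delta-delta-Ct method,
    off-target and paralog-compensation diagnostics,
    misclassification-corrected (false-positive/false-negative adjusted)
    essential-gene proportion estimation, resampling null distributions
    from old-gene pools, and exact contingency tests. A seeded synthetic
    screen simulator with known ground truth drives end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
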