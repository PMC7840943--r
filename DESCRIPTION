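Package: mrcoloc
Title: Two-Sample Mendelian Randomisation and Colocalisation for
    Transcriptome-Wide Gene Prioritisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritises genes whose genetically predicted expression affects
    disease risk by combining two-sample Mendelian randomisation (Wald ratio
    and inverse-variance-weighted estimators) on eQTL and GWAS summary
    statistics with Bayesian colocalisation via approximate Bayes factors,
    approximate conditional analysis from an LD reference, and Steiger
    directionality filtering. Includes cis-instrument selection with greedy LD
    clumping, cross-tissue heterogeneity and tissue-specificity (tau) analyses,
    brain-versus-blood estimate comparison, a fully seeded synthetic
    summary-statistics generator with known causal truth for calibration, and
    an end-to-end pipeline driver with plain TSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'sumstats-io.R'
    'conditional.R'
    'coloc.R'
    'harmonise.R'
    'instruments.R'
    'mr-core.R'
    'mrcoloc-package.R'
    'simulate.R'
    'tissue.R'
    'steiger.R'
    'pipeline.R'
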