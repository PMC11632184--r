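Package: ancmix
Title: Ancestry Mixing Proportions from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the ancestry mixing proportions of a genome-wide
    association study (GWAS) from summary statistics alone, given a
    multi-population reference panel. Implements three estimators: a
    covariance-based allele-frequency estimator computed over
    quasi-independent SNP sets ('afmix'), a simplex-constrained
    least-squares allele-frequency estimator ('summix'), and a Z-score-only
    estimator that regresses products of association Z-scores on
    per-population genotype correlations ('zmix'), together with an
    unconstrained consecutive-pair baseline ('zmix_legacy'). Also provides
    a hierarchical Balding-Nichols reference-panel generator, a GWAS cohort
    and null Z-score simulator, summary-statistics harmonization against a
    panel SNP index, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
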