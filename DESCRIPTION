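Package: cmassoc
Title: Control-Marker-Corrected Association Testing in Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linkage-disequilibrium association testing for quantitative
    traits in admixed populations. Implements a regression test whose
    spurious (stratification-driven) covariance component is removed using
    a single control marker chosen for its excess of observed over
    Hardy-Weinberg-expected genotypic variance, together with the two
    standard comparison analyses (uncorrected simple regression and
    multiple regression on population membership), exact two-locus
    population-genetic theory with noncentral-t power prediction, an
    admixture simulator for replicate studies, Hardy-Weinberg structure
    diagnostics, and a genome-wide eQTL scan layer with peak calling and
    cis/trans classification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
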