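Package: mycovar
Title: Demography-Aware Consensus Differential Abundance for the Tumor
    Mycobiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing demography-dependent variability in
    tumor fungal abundance from sparse sequencing count data. Implements
    a consensus differential-abundance framework that requires a species
    to be significant under every combination of four compositional
    transformations (CLR, CLR with multiplicative zero replacement,
    relative abundance, log-CPM with quantile normalization) and four
    unsupervised batch corrections (ComBat, batch mean centering, an
    MMUPHin-like log-linear shrinkage, PLSDA component removal), with
    confounding controlled by inverse probability of treatment weighting
    from logistic propensity scores. Also provides a normalization
    artifact audit for near-all-zero features, cross-cohort read-count
    concordance statistics based on disjoint genus-pair ratio
    resampling, and a synthetic cohort generator with planted effects
    for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    stats,
    sva,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
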