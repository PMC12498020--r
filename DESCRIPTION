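Package: cryptpc
Title: Cryptic Ancestry Signatures on Marginal Principal Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects population-differentiating ancestry signals that are
    invisible on the leading principal components of a genotype matrix.
    Provides readers and writers for EIGENSTRAT and PLINK-text genotype
    data, an ancient-DNA quality-control cascade (minor allele frequency,
    Hardy-Weinberg exact test, missingness, linkage-disequilibrium pruning,
    kinship), principal component analysis with deterministic sign
    conventions, systematic screening of every component for
    population-extreme values and group discrimination (including an
    exhaustive search over three-way component combinations), distance
    gradients in a selected component subspace with Ward clustering and
    classical multidimensional scaling, a simplified f4-statistic based
    admixture-proportion estimator with block-jackknife errors, a rank
    test for the number of ancestry streams, model selection over
    candidate source sets, block-bootstrap confidence intervals, and a
    Balding-Nichols admixture simulator used to validate every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
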