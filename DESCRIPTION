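Package: ricewue
Title: Multi-Trait Water-Use-Efficiency Analysis for Rice Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genotype-by-treatment phenotyping experiments
    that contrast ponded-water and limited-water irrigation in rice. Implements
    Cohen's d effect-size screening, Welch two-sample tests, balanced two-way
    ANOVA, trait correlation structure, and correlation-matrix PCA; a
    from-scratch NIPALS partial-least-squares regression with
    variable-importance-in-projection (VIP) scores for ranking traits against
    leaf carbon-isotope composition; a Composite Multi-Trait Index (CMTI) with
    directional 0-1 normalization and a deterministic split of genotypes into
    inherently stable versus adaptively plastic water-use strategies; derived
    trait arithmetic (stomatal and papillae densities, detached-leaf water
    loss, dry-down field-capacity targets, yield and milling metrics); ATR-FTIR
    band indices for cuticular wax and flavonols; and a synthetic
    genotype-by-treatment trait generator with planted effect sizes for
    validating every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
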