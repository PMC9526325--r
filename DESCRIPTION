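Package: famhist
Title: Family-History-Aware Association Testing for Binary Traits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and association-testing toolkit for incorporating
    relatives' disease history into case-control genetic association studies.
    Implements the liability-threshold family-history phenotype (posterior
    mean genetic liability conditional on an individual's own case-control
    status and the statuses of parents and siblings), a kinship-weighted
    inverse-variance meta-analysis that combines a probands' logistic
    regression with a relatives' logistic regression, and a standard
    case-control logistic regression baseline. Includes a pedigree simulator
    (nuclear and three-generation families, Hardy-Weinberg founders, gene
    dropping, exact kinship matrices), a liability-scale phenotype simulator
    with polygenic and age-by-genotype interaction components, replicate
    engines for type-I-error and power studies with exact binomial
    confidence intervals and genomic-control inflation factors, and
    PLINK-style PED/MAP and phenotype TSV import/export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
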