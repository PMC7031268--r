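Package: domvar
Title: Dominance Genetic Variance and Dominance-Aware Association Mapping
    for Low-Heritability Fertility Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetics toolkit for estimating dominance genetic
    variance and mapping loci with dominance effects in livestock data with
    low-heritability traits such as dairy-cattle female fertility. Provides
    PLINK text genotype input/output with marker quality control, pedigree
    utilities (topological sorting, inbreeding coefficients, numerator
    relationship matrices), VanRaden additive and heterozygosity-deviation
    dominance genomic relationship matrices, an average-information REML
    engine for arbitrary variance-component models with weighted residuals,
    phenotype editing and sire-model pre-correction of fixed effects, a
    mixed-model association scan with genotype-class fixed effects and a
    two-step additive/dominance significance test under false-discovery-rate
    control, and a gene-drop simulation framework for evaluating the power
    and precision of dominance-QTL detection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
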