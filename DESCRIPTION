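Package: trioverlap
Title: Composite-Null Tests of Genetic Overlap Between Disease Subgroups
    from Case-Parent Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genetic variants that influence risk of two disease
    subgroups simultaneously, using summary statistics from case-parent
    trio studies. Provides the additive genotypic transmission
    disequilibrium test (gTDT) with its conditional-logistic closed form,
    inverse-variance weighted fixed-effects meta-analysis across studies,
    and a product-of-Z-scores test of the composite null hypothesis that
    at most one subgroup is associated, with p-values from the tail of the
    normal product distribution. Includes an ascertained bi-ethnic
    case-parent trio simulator under a multiplicative relative-risk model,
    a type-I-error and power evaluation harness, genomic-inflation and QQ
    diagnostics, VCF/FAM trio input, and distance/LD locus clumping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    survival,
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
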