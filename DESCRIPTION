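Package: pigbias
Title: Hair Pigmentation Bias in Hair Cortisol Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and correct hair-pigmentation bias in hair
    cortisol and cortisone measurements. Builds an ancestry-adjusted polygenic
    hair-colour score from pigmentation SNP dosages in a training split,
    predicts Box-Cox-transformed hair hormone concentrations with
    principal-component ancestry correction, and screens the pigmentation SNPs
    for pleiotropy with inverse-variance heterogeneity statistics (Cochran's Q,
    I-squared, Egger asymmetry). Includes a synthetic admixed-cohort generator
    (Balding-Nichols allele frequencies with Dirichlet admixture) that realizes
    the competing causal scenarios - local hair effect, population
    stratification, minority stress - so the pipeline's ability to distinguish
    them can be demonstrated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    RSpectra
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    car,
    metafor
Config/testthat/edition: 3
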