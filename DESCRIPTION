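Package: eigdim
Title: Dimensionality of Genomic Information, Mixed-Model GWAS, and
    Single-Step Genomic Prediction on Simulated Populations
Version: 0.1.0
Authors@R:
    person("Quantitative Genetics", "Tools", email = "qgtools@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time simulation of livestock-like populations with a
    polygenic trait, construction of genomic relationship matrices and their
    eigenvalue profiles (the EIGx machinery linking the number of largest
    eigenvalues of G to effective population size and genome length),
    EMMAX-style mixed-model genome-wide association on sequence panels,
    preselection of variants for chip augmentation, and single-step GBLUP
    (ssGBLUP) and pedigree BLUP evaluation with H-inverse assembly, blending,
    and validation metrics (accuracy and dispersion of genomic breeding
    values).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
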