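Package: relquartet
Title: Relatedness Coefficients for Triplets and Quartets of Marker Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probability models and estimators for identity-by-descent
    relatedness between pairs of diploid individuals measured at two, three,
    and four marker genes per locus. Implements the nine Jacquard condensed
    identity modes, the eight relatedness coefficients they induce
    (inbreeding coefficients, pairwise kinship, three-gene coefficients,
    and the four-gene coefficients H, F_AB and R_AB that require cumulants),
    exact genotype-pair class probabilities at multiallelic loci,
    method-of-moments and closed-form joint estimators, maximum-likelihood
    estimation across loci by expectation-maximization over latent identity
    modes, a genotype-pair simulator including population mixtures that
    induce identity disequilibrium, and exact sampling variances of
    single-locus estimators by full enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
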