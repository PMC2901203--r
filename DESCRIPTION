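Package: bgfmap
Title: Bayesian Gene-Frequency Model for Fine Mapping QTL Using Linkage
    Disequilibrium
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fine mapping of a biallelic quantitative trait locus (QTL)
    within a ~1 cM region from dense SNP haplotypes of unrelated
    individuals. Implements the Bayesian gene-frequency (BGF) model, in
    which the conditional mean and variance of the unobserved QTL genotype
    are modeled as functions of the conditional QTL allele frequencies on
    marker haplotypes, with a logit-normal prior on those frequencies and a
    Metropolis-Hastings within blocked Gibbs sampler over effect, location,
    frequencies and residual variance. Also provides the least-squares
    haplotype regression scan used as a comparator, a forward-in-time
    Wright-Fisher simulator that generates linkage disequilibrium by
    random mating with mutation, and a power/precision evaluation harness
    with null-calibrated critical values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
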