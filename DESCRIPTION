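Package: snaherit
Title: Quantitative Genetics of Social Network Traits from Dyadic Fight Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives social-network behaviour traits (degree, weighted degree,
    betweenness, closeness, eigenvector centrality and clustering coefficient)
    from post-mixing dyadic fight records in group-housed pigs, and estimates
    their heritabilities, common-pen effects and genetic correlations with
    performance traits using a Bayesian pedigree-based animal model fitted by
    Gibbs sampling. Includes pedigree kinship machinery (inbreeding, the
    additive relationship matrix and its sparse inverse), posterior
    summarisation with highest posterior density intervals, and a synthetic
    data generator that emulates the study design of a commercial pig herd so
    that every stage of the pipeline can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
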