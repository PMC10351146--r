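Package: kinocs
Title: Kinship Matrices for Optimum Contribution Selection in Genomic
    Breeding Program Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of a closed dairy-cattle breeding
    program under optimum contribution selection (OCS), comparing genomic
    relationship matrices (VanRaden methods 1 and 2 under several reference
    allele frequency policies) against the pedigree numerator relationship
    matrix.  Includes a Wright-Fisher historical population simulator with
    recurrent mutation, meiosis with founder-segment identity-by-descent
    tracking, PBLUP/GBLUP/ssGBLUP breeding value prediction via mixed-model
    equations, cardinality-constrained OCS with a pseudofemale aggregate,
    drift/homozygosity inbreeding decomposition, genic variance, and a
    trend-regression scenario comparison with Bonferroni-corrected pairwise
    slope tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
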