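Package: ocsim
Title: Forward Simulation of Genomic Inbreeding Management Under Optimum
    Contribution Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward-in-time stochastic breeding simulation for comparing
    genomic relationship matrices in the management of inbreeding and
    genetic diversity.  Simulates a neutral Wright-Fisher historic
    population with linkage, samples SNP, neutral-locus and QTL panels,
    tracks uniquely coded founder alleles through Poisson (Haldane)
    meiosis, and runs GBLUP-based optimum contribution selection under a
    group-coancestry constraint.  Implements VanRaden method I,
    runs-of-homozygosity, linkage-analysis (segregation-indicator
    gene-dropping) and true identity-by-descent relationship matrices,
    together with drift- and homozygosity-based inbreeding coefficients,
    genic and breeding-value variance, rate-of-inbreeding regression and
    Lin's concordance correlation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
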