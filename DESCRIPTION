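Package: dupscan
Title: Detection, Classification and Molecular Evolution of Gene Duplicates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Phylogenomic toolkit for detecting gene duplicates in annotated
    genomes by translated homology search, classifying their duplication
    mechanism (RNA- versus DNA-mediated) from retained intron structure,
    calling pseudogenes from premature stops and truncations, collapsing
    copies across species into independent duplication events by flanking-gene
    synteny, and characterizing their mode of evolution with neighbor-joining
    bootstrap phylogenies, Goldman-Yang codon models (one-ratio and two-ratio
    branch models with likelihood-ratio tests) and turnover Z-tests. Includes
    a synthetic annotated-genome simulator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
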