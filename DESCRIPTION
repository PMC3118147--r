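Package: phasemir
Title: Phased MIR159/319 Stem-Loop Analysis: Homolog Filtering, Partitioned
    Small-RNA Quantification, PARE Profiling and Doublet-Model Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of phased, loop-to-base processed plant
    microRNA precursors of the MIR159/319 type. Provides stem-loop hairpin
    representation with a deterministic stacking-aware folder and dot-bracket
    parsing; mature-miRNA homolog scanning with the seven modified miRcheck
    filtering rules; five-type precursor classification and construction of
    the nine-partition scheme (sp1, miR*, sp2, ACR5, sp3, ACR3, sp4, miR,
    sp5); perfect-match small-RNA mapping with mean-total normalization,
    80-percent-overlap partition assignment, leak accounting and
    mutant-to-wild-type ratios; PARE (degradome) cleavage profiling in TP10M
    units; structural-alignment consensus with covariation-classified
    base-pair detection; a partitioned GTR plus 16-state doublet
    substitution model with discrete-gamma rates, Felsenstein pruning,
    Metropolis-Hastings MCMC and majority-rule consensus; gene-tree and
    species-tree LCA reconciliation counting duplications and losses; and
    seeded synthetic-data generators for every input class so the whole
    pipeline is exercisable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
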