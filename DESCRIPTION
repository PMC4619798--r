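Package: homoplex
Title: Homophily-Driven Evolutionary Game Dynamics on Multiplex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the emergence of cooperation on multiplex
    (multilayer) social networks in which imitation is shaped by homophily
    and by interlayer communicability. Builds homophily-weighted layer
    matrices and supra-adjacency matrices, computes the global heterogeneous
    eigenvector-like centrality of the multiplex via a Khatri-Rao supra
    matrix, identifies the critical mass (the smallest, most central and
    most homophilous coalition able to seed a behaviour), computes the
    multiplex communicability matrix exp(Z_L + C_LL), and runs Monte Carlo
    Prisoner's Dilemma dynamics with a Fermi imitation rule whose noise is
    sharpened by homophily and whose adoption rate is scaled by interlayer
    communicability. Includes a generator for synthetic scale-free
    multiplexes with normally distributed homophily differences, experiment
    drivers, plain-text readers/writers for multilayer edge lists, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    methods,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
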