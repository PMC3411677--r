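Package: specnet
Title: Spatial Spectral Network Generation with Tunable Structure
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates spatial random networks with tunable clustering,
    degree assortativity, fragmentation and mean degree. Node positions are
    synthesised by spectral (1/f^gamma) scaling of a Gaussian random field on
    a toroidal grid; links are drawn one by one with probability decaying in
    toroidal distance under a generalized-normal dispersal kernel, with a
    focal-node class whose connections to regular nodes are up-weighted to
    produce disassortative (hub-like) structure. Includes the four structure
    measures used to characterise such networks (average local clustering,
    Newman degree assortativity, fragmentation index, mean degree), a
    non-spatial configuration-model comparator with triangle building, a
    full-factorial parameter-sweep protocol with quantile tables and
    factorial ANOVA decomposition, and a grid-search fitter that regenerates
    networks matching target structure measures, as used for livestock
    contact networks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, stats, utils, graphics
Suggests: testthat (>= 3.0.0), igraph, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
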