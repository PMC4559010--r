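Package: opmapr
Title: Optical Genome Map Simulation, Assembly and Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nanochannel optical genome mapping studies: in-silico
    nicking-endonuclease digestion of genome sequences with resolution-aware
    label-density estimation and enzyme selection, simulation of mega-sized
    labelled DNA molecules under an explicit error model (false-positive and
    false-negative labels, sizing noise, per-molecule stretch, pixel
    quantization), consensus genome-map assembly by overlap clustering,
    progressive layout and kernel-density peak calling, dynamic-programming
    alignment of label maps with error-aware scoring, and the descriptive
    statistics (N50, label density, depth titration, coverage) used to QC a
    whole-genome map. Includes minimal text readers and writers for
    BNX-style molecule files and CMAP-style map files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
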