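Package: trophicmotifs
Title: Trophic Coherence, Triad Significance Profiles and Motif Families in
    Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the local and global structure of directed
    food webs (links pointing from prey to predator). Computes trophic levels
    and the trophic incoherence parameter q, counts the 13 connected
    three-species triads and scores their significance against a
    degree-preserving edge-swap null model, compares webs by the Pearson
    correlation of their normalised triad significance profiles, clusters webs
    into motif families by UPGMA, and generates synthetic food webs with
    tunable trophic coherence via a preferential-preying assembly model whose
    temperature parameter can be calibrated to an empirical incoherence value
    by stochastic root finding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
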