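Package: markerptp
Title: Barcoding Marker Discovery and Poisson Tree Processes Species
    Delimitation for Plastome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and evaluating DNA barcoding markers from
    whole-plastome multiple sequence alignments. Extracts single nucleotide
    polymorphism (SNP) positions, computes windowed SNP density with a
    z-score based variability classification, proposes candidate marker
    regions, builds neighbor-joining trees with bootstrap support, performs
    single- and multi-rate Poisson Tree Processes (PTP) species delimitation
    by maximum likelihood (with a likelihood ratio test against a one-rate
    null) and by Markov chain Monte Carlo (per-node supports and the Average
    Support Value), and scores each marker by its species-discrimination
    success. A coalescent-style simulator with regional mutation-rate
    hotspots generates alignments, trees and ground truth so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
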