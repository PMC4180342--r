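Package: switchfold
Title: Sequence and Structure Analysis of Fold-Switching (Chameleon) Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for investigating protein sequences that are nearly
    identical yet adopt different folds (for example a three-helix bundle
    versus a four-stranded beta-sheet plus alpha-helix). The package builds
    inter-residue average-distance statistics from reference structures,
    samples random C-alpha chain conformations by Metropolis Monte Carlo
    under the resulting distance potential, and converts the sampled
    contacts into per-residue contact-frequency (F-value) profiles whose
    peaks mark putative folding-initiation sites. It also provides local
    sequence-tendency scoring of chimeric sequences against their two
    parents, conservation analysis of multiple alignments with
    hydrophobic-conservation marks, a prose-recipe fold classifier, and an
    orientation-dependent C-alpha Go model with Q-value tracking and
    transition-state contact maps. A synthetic-data generator emulates
    every required input class so the full pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
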