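Package: rnamotiflib
Title: Motif-Constrained RNA Library Design with Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design libraries of RNA sequences from partially constrained
    sequence and secondary-structure motifs. A design space is written as a pair
    of constraint strings over the nucleotide and dot-bracket alphabets extended
    with single-position (?) and variable-length (?*) wildcards. Fixed-length
    tasks are sampled from the space and unconstrained positions are filled by a
    reinforcement-learning agent (or a uniform random agent) so that the folded
    candidate satisfies the structure constraints, an optional GC-content
    objective, or a plug-in score. Includes a dependency-free Nussinov folding
    engine, an interface to ViennaRNA's RNAfold (MFE and MEA), a masked-corpus
    training-data generator, a Weisfeiler-Lehman structure distance, local
    refinement steps, and a transcriptional theophylline-riboswitch design
    protocol with library reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
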