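Package: crmscout
Title: Alignment-Free Cross-Species Discovery of Cis-Regulatory Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised, alignment-free prediction of cis-regulatory modules
    (CRMs, enhancers) in diverged genomes. Trains k-mer statistical scorers
    (a smoothed fifth-order Markov chain, an interpolated Markov model, and a
    Poisson word-count score) on a set of known CRMs versus background
    sequence, scans a target genome in sliding windows, calls candidate CRMs
    by global and local score rank near genes of a homology-mapped expression
    gene set, and assesses predictions with a hypergeometric enrichment test.
    Also provides position-weight-matrix binding-site annotation and Regulus,
    a probabilistic hidden-Markov-model score of motif-composition similarity
    between two unalignable sequences, together with a fully synthetic,
    seed-reproducible benchmark generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
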