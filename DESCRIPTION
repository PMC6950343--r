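Package: prcx
Title: Profile Hidden Markov Model Comparison and UPGMA Trees of Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares profile hidden Markov models (pHMMs) against each other
    by co-emission alignment scoring over a five-state pair hidden Markov
    model (forward and Viterbi variants, local or global), reads and writes
    the HMMER3 text profile format, builds pHMMs from single or aligned FASTA
    sequences with substitution-matrix or sequence context-specific
    pseudocounts, accelerates all-vs-all comparison by discretizing profiles
    to a 219-letter column-state alphabet scored with affine-gap
    Smith-Waterman, converts co-emission scores to distances, and constructs
    ultrametric UPGMA phylogenetic trees with an O(n^2) agglomeration,
    emitting PHYLIP distance matrices and Newick trees. Includes a protein
    family simulator with known generating phylogeny for end-to-end
    validation, and slow reference implementations of the alignment and tree
    algorithms for independent verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    methods,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
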