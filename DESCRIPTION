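Package: maskedBWT
Title: Space-Efficient k-mer Set Indexing via Masked Superstrings and the
    Masked Burrows-Wheeler Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents an arbitrary set of DNA k-mers as an approximately
    shortest masked superstring (a superstring plus a bit mask selecting the
    represented k-mer occurrences), indexes it with the Masked Burrows-Wheeler
    Transform, and serves exact membership queries, compressed-dictionary
    (minimal-perfect-hash style) Lookup/Access queries, and kLCP-accelerated
    streamed queries over both the unidirectional and the bidirectional
    (reverse-complement-aware) k-mer models. Includes a global greedy
    superstring heuristic, min-one/max-one mask optimization, theoretical
    space accounting, case-encoded masked-superstring FASTA input/output, a
    synthetic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
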