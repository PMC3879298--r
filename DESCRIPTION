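Package: metasig
Title: Alignment-Free Comparison of Metagenomic and Metatranscriptomic Read Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Alignment-free beta-diversity analysis of next-generation sequencing
    read sets. Builds k-tuple (k-mer) sequence signatures counting both strands,
    fits order 0-3 Markov background models, and computes eight dissimilarity
    measures between samples (d2, d2S, d2*, Manhattan, Euclidean, Chebyshev, the
    CVTree composition-vector measure, and the relative-entropy measure S2).
    Includes the downstream evaluation toolkit used with such measures (UPGMA
    clustering, symmetric-difference tree comparison, principal coordinates
    analysis with goodness of fit, Spearman gradient correlation), read
    subsampling and sequencing-error injection protocols, and a synthetic
    community generator with planted group structure and mixture gradients so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
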