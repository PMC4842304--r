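Package: esagdi
Title: Enhanced Suffix Array Genome Index with Guide, Discriminating-Character
    and Integrated Layouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds enhanced suffix array (ESA) indexes over DNA sequences for
    exact pattern counting and locating. Implements bytecoded longest-common-
    prefix (LCP) and child arrays with exception guide (EG) arrays for fast
    random access, blockwise 64-value bitpacked integer vectors, a
    discriminating-character (DC) array that removes suffix-array and genome
    lookups during child-interval selection, and an integrated layout that
    interleaves LCP, child and DC information in 5-byte blocks. Includes FASTA
    ingestion, synthetic genome and query generation, index serialization, and
    a benchmark harness for the count/locate protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
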