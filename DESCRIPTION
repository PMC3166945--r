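Package: kbloom
Title: Memory-Frugal k-mer Counting with a Bloom Filter Staging Area
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact counting of DNA k-mers that occur at least c times in
    sequencing reads, using a Bloom filter (or counting Bloom filter for
    c > 2) as a staging area so that singleton, mostly error-derived,
    k-mers never enter the hash table. A first pass stages all observed
    canonical k-mers implicitly in the filter and tables only those seen
    at least c times (plus an analytically predictable set of false
    positives); a second pass recounts the tabled k-mers exactly and
    prunes the false positives. Includes the analytic machinery (Bloom
    false-positive rate, optimal hash count, expected error-derived
    k-mers as a function of coverage), a shotgun-read simulator with a
    uniform substitution error model, a brute-force counting oracle, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    data.table,
    tibble,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
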