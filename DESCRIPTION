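Package: ribospacer
Title: Typing and Comparative Analysis of Bacterial 16S-23S rRNA Intergenic Spacers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the 16S-23S rDNA intergenic spacer (ITS)
    of bacteria, with defaults tuned to sphingomonads. Covers in-silico PCR with
    degenerate primers and excision of the spacer from rRNA operon fragments,
    rule-based detection of tRNA genes by cloverleaf-structure search, spacer
    typing by tRNA content and order, partition into ITS-1/ITS-2/ITS-3,
    alignment-based conservation, conserved-block and indel analysis,
    Jukes-Cantor distance / neighbour-joining / maximum-likelihood phylogeny
    with bootstrap consensus, hairpin folding of ITS-2, and a seeded generator
    of synthetic operon panels with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
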