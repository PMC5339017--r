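Package: sbhdesign
Title: Design of Spacer-Blocking-Hairpin and Inducible sgRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering conditional CRISPR single guide RNAs based on
    spacer-blocking hairpins (SBH). A 5' back-fold extension complementary to the
    guide spacer folds the sgRNA into a quiescent hairpin; replacing the hairpin
    loop with an RNA-cleaving unit (endoribonuclease motif, antisense-oligonucleotide
    sensing loop, or ribozyme) yields inducible guides (iSBH). The package provides
    a deterministic construct grammar (back-folds, bulged stems, unit grafts),
    a built-in nearest-neighbour minimum-free-energy folding engine with
    partition-function pair probabilities, folding scores against expected hairpin
    structures, systematic enumeration of SBH(x) series and sliding bulge patterns,
    exhaustive and genetic-algorithm evolution of shared ASO-sensing loops across
    multiple spacers, and cloning-oligo generation with U6 +G1 handling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
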