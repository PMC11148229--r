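Package: archetypeR
Title: Archetype Analysis of Functional-Gene Sequence Compilations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the diversity and biogeography of
    functional-gene sequence compilations such as nosZ, the nitrous oxide
    reductase gene. Implements greedy identity clustering into operational
    taxonomic units (OTUs), majority-rule consensus calling, six-frame ORF
    finding and translation, progressive protein alignment with
    back-translation, discriminative 70-mer window discovery ("probe
    finding"), archetype clustering, nearest-reference clade classification,
    and habitat-partitioning summary statistics, together with a seeded
    synthetic-compilation generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
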