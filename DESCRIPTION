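Package: mitochar
Title: Characterization of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative characterization of circular
    mitochondrial genomes of the kind routinely reported for vertebrate
    mitogenomes: wrap-aware gene-organization accounting on the circle
    (gene lengths, intergenic spacers, overlaps, strand census, the
    protein-coding union), base composition with AT/GC strand-asymmetry
    skews, vertebrate-mitochondrial translation with start and
    incomplete-stop classification, relative synonymous codon usage
    (RSCU), control-region tandem-repeat counting, alignment-based
    polymorphic-site and amino-acid substitution censuses, a
    four-site cytochrome b haplotype classifier, and Tamura-Nei (TN93)
    distance / neighbor-joining / bootstrap phylogenetics with outgroup
    rooting and Newick output. A seeded synthetic-genome generator
    provides pig-like mitogenomes with known truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
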