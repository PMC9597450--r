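Package: bandkaryo
Title: Dominant-Marker Diversity and Karyotype Asymmetry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genetic-diversity studies that combine dominant
    multilocus fingerprints (ISSR, SCoT, SDS-PAGE protein profiles) with
    classical cytogenetics. Reads and validates binary band matrices,
    classifies bands (monomorphic, polymorphic, genotype-specific), and
    computes per-primer informativeness indices (polymorphism percentage,
    PIC, effective multiplex ratio, marker index, resolving power).
    Estimates dominant-marker population-genetic summaries under
    Hardy-Weinberg equilibrium (Na, Ne, Shannon I, He, uHe). Derives the
    full set of karyotype asymmetry parameters from chromosome arm
    measurements (TF%, AsK%, centromeric index, Watanabe A and MCA,
    Romero-Zarco A1/A2, Stebbins category, karyotype formula, ideograms).
    Provides Dice similarity, UPGMA dendrograms and principal-coordinate
    ordination, constructive synthetic-data generators whose summary
    statistics hit user-specified targets exactly, and a reproducible
    end-to-end pipeline with report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
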