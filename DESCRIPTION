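Package: barcodegap
Title: Impact of Incomplete DNA Barcode Reference Libraries on Benthic
    Ecological Status Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify how gaps in DNA barcode reference libraries
    (BOLD, GenBank) distort biodiversity descriptors and ecological quality
    assessment of transitional-water benthic macroinvertebrate communities.
    Builds "reduced" community databases restricted to barcoded species,
    computes species richness, Shannon diversity, the AMBI benthic biotic
    coefficient and the multivariate M-AMBI score, classifies sites into the
    five Water Framework Directive quality classes, and compares
    classifications between the full (morphological) and reduced databases.
    A companion sequence toolkit builds majority-rule consensus sequences,
    Kimura 2-parameter distances, neighbor-joining trees, maximum-likelihood
    Poisson Tree Processes species delimitations, and IUPAC-aware degenerate
    primer matching. Synthetic-data generators emulate a regional survey and
    COI accession sets so every stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
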