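Package: varminer
Title: Mining Genetic Variant Mentions from Articles, Tables and
    Supplementary Material
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how much curated genetic-variant information
    can be recovered by text mining from the different parts of a
    publication: the abstract, the full-text narrative, tables, and
    supplementary files. Provides a pattern-based extractor for variant
    and gene mentions, a normalizer to HGVS nomenclature with
    configurable equivalence relaxations, recall metrics against a
    curated variant database (overall, gene-relaxed, and restricted to
    commonly covered articles), a MeSH-tree classifier separating
    high-throughput from conventional studies, and a synthetic corpus
    generator whose ground-truth manifest makes every downstream metric
    analytically checkable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
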