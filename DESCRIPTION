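Package: ratecov
Title: Integrated Evolutionary Rate Covariation Across Clades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes evolutionary rate covariation (ERC) between genes from
    per-clade branch-length tables: relative evolutionary rates (RERs) by
    centered log-ratio normalization against the genome-wide branch profile,
    per-clade Pearson correlation of RER profiles, Fisher z transformation
    weighted by branch count, and summation across independent clade datasets
    into integrated FtERC scores. Includes permutation tests for elevated mean
    ERC within and between gene sets, top-quantile occurrence enrichment with
    signed fold changes and chi-squared tests, a protein-complex coevolution
    benchmark against representation-matched simulated complexes with
    Benjamini-Hochberg FDR and precision-recall fold-change curves, and a
    synthetic multi-clade data generator with known coevolving modules for
    calibration and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
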