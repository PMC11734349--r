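Package: sartransfer
Title: Analogue Series Alignment and SAR Transfer with Context-Dependent
    Fragment Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts potency-ordered analogue series from compound-activity
    tables by single-cut matched-molecular-pair fragmentation, quantifies
    substituent similarity both conventionally (Morgan fingerprint Tanimoto
    averaged with molecular quantum number descriptor similarity) and
    context-dependently (continuous-bag-of-words embeddings trained on
    series treated as sentences), aligns series by dynamic programming with
    zero gap penalty, searches a series database for structure-activity
    relationship transfer partners and proposes transfer analogues, and
    projects fragment-embedding space onto a property-annotated 2D grid map
    via principal components, t-distributed stochastic neighbour embedding
    and optimal linear assignment. Includes a synthetic-fixture generator
    producing scaffold/substituent combinatorial series with planted potency
    gradients and planted transfer partners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
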