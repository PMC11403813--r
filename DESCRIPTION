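Package: cccnet
Title: Ensemble Inference of Cell-Cell Communication Networks from
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("cccnet", "developers", email = "cccnet@example.org",
           role = c("aut", "cre"))
Description: Infers cell-cell communication networks from single-cell
    RNA-seq count matrices by scoring curated ligand-receptor pairs
    (including multi-subunit complexes) between every pair of annotated
    cell types with three independent scoring engines, assessing
    significance with cell-type label permutation tests, and fusing the
    per-engine results through Fisher's combined probability test
    together with a shared-test-count normalised communication score.
    Downstream utilities build the weighted directed cell-type graph and
    compute PageRank importance, the largest communication clique,
    modularity clustering, and cross-method agreement statistics.  A
    negative-binomial simulator with planted ligand-receptor channels
    makes the whole pipeline testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
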