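Package: screenstate
Title: Pooled CRISPRi Drug-Modifier Screen Scoring and Single-Cell Tumor
    State Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores pooled genome-wide CRISPRi drug-modifier screens from
    sgRNA count tables: growth (gamma), drug (tau) and drug/growth ratio
    (rho) phenotypes centered on non-targeting controls and normalized by
    population doublings, gene-level aggregation as the mean of the top
    sgRNAs, Mann-Whitney tests against the non-targeting control
    distribution, replicate Wald tests, Benjamini-Hochberg false discovery
    control, and integration of conserved hits across a human and a mouse
    screen. Also assigns single tumor cells to the four glioblastoma
    meta-module states (MES-like, AC-like, OPC-like, NPC-like), calls
    cycling cells from cell-cycle module scores, scores arbitrary gene
    signatures against bin-matched control genes, and compares groups of
    cells with rank-sum tests. Seeded synthetic-data generators produce
    screen count tables and single-cell expression matrices with known
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
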