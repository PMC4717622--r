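Package: synlethal
Title: Mining Multi-Omic Cancer Data for Candidate Synthetic Lethal Gene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Enriches for candidate synthetic lethal gene pairs in matched
    gene-expression and mutation matrices from cancer cell-line or tumour
    panels. Loss-of-function is inferred at multiple molecular levels:
    deleterious mutation, copy-number loss, and loss of mRNA expression
    visible as bimodality or non-normality. Bimodal expression profiles are
    detected with a two-component Gaussian-mixture bimodality index combined
    with a gap-based midpoint locator, and samples are partitioned into low
    and high expression modes with an adaptive unassigned window. Three
    workflows mine gene pairs whose loss-of-function calls are mutually
    exclusive: a genetic-only Fisher exact screen over mutation calls, an
    expression-only screen over bimodal-low modes ranked by a separation
    score, and an integrated screen testing mutation enrichment in the high
    expression mode of a bimodal partner. Candidates can be annotated with a
    graph-based (Wang) semantic-similarity functional-redundancy score from
    user-supplied ontology files, and evaluated with permutation enrichment
    against reference pair sets, gene-set Fisher enrichment, and rank-sum
    dependency tests against knock-down phenotype scores. A synthetic
    multi-omic data generator with planted ground truth supports end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
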