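Package: treesem
Title: Tree-Based Structure Learning for Gene Networks with Structural
    Equation Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recovers undirected and directed trees from gene-expression
    data and/or a reference interaction network: Kou's Steiner-tree
    heuristic for seed-based active-module detection, Prim's minimum
    spanning tree, causal additive trees (CAT) via bivariate penalized
    spline regression and the Chu-Liu-Edmonds minimum arborescence, and a
    Chow-Liu/CPDAG polytree learner. Includes graph weighting schemes
    (1-|cor|, Fisher r-to-z differential co-expression p-values), minimax
    linkage clustering with prototypes for node merging, SEM-style group
    perturbation statistics on recovered trees (node activation and
    inhibition, average causal effects along directed paths), enrichment
    metrics, and generators for case/control co-expression simulation
    studies.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    mgcv,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
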