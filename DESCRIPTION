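Package: greedgene
Title: Hybrid Genetic-Exhaustive Descriptor Selection and 2D-QSAR
    Modeling for Sigma-2 Receptor Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based 2D-QSAR workflow for Sigma-2 receptor (S2R)
    binding affinity. Curates ligand collections (molecular-weight, affinity,
    basic-nitrogen, stereochemistry and scaffold filters), converts Ki to pKi,
    computes open-toolkit 2D descriptor analogs (Balaban J, longest
    single-bond chain, charge- and logP-binned van der Waals surface areas),
    screens and decorrelates descriptor matrices, and selects fixed-size
    descriptor subsets by forward stepwise regression, the lasso path, a
    genetic algorithm, or GreedGene, a hybrid that completes a consensus core
    from repeated GA runs by exhaustive search with correlated-descriptor swap
    refinement. Models are multivariate linear regressions validated by
    leave-one-out Q2 under a repeated 4:1 split protocol. A virtual-screening
    stage applies Lipinski and applicability-domain filters, scores libraries
    with a fitted or published model, selects decoys by maximum Tanimoto
    dissimilarity, and reports sensitivity, specificity and enrichment
    factors. A synthetic-data generator with planted linear structure makes
    every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
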