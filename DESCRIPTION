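Package: coexmod
Title: Weighted Coexpression Modules, Module Preservation and Module-Level
    Differential Expression for Multi-Tissue Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for weighted gene coexpression network analysis of
    multi-tissue bulk expression data: soft-thresholded correlation networks,
    topological overlap, adaptive tree-cut module detection with eigengenes
    and module membership (kME), module-trait association maps, cross-dataset
    module preservation via permutation Z statistics (Z_summary), a
    module-level differential-expression test (modDE) that combines per-gene
    evidence with direction-of-effect consistency against the module
    correlation structure, signature enrichment (hypergeometric overlap,
    preranked GSEA, single-sample GSEA), classical MDS sample maps, and a
    synthetic multi-tissue data generator with planted module structure for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
biocViews: Network, GeneExpression, DifferentialExpression, GraphAndNetwork,
    GeneSetEnrichment
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'dataio.R'
    'enrichment.R'
    'netbuild.R'
    'modules.R'
    'modde.R'
    'synthdata.R'
    'preservation.R'
    'traitmap.R'
    'pipeline.R'
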