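#' @import methods
#' @importFrom stats cor sd var median quantile phyper pt qnorm p.adjust
#'   hclust cutree as.dist cmdscale dist rnorm runif setNames prcomp
#'   complete.cases
#' @importFrom utils read.delim write.table head packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
NULL

#' Accessor generics
#'
#' Small family of accessor generics used across the package's S4 classes.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The corresponding slot content; see the class man pages.
#' @name coexmod-generics
NULL

#' @rdname coexmod-generics
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))

#' @rdname coexmod-generics
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname coexmod-generics
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname coexmod-generics
#' @export
setGeneric("datasetLabel", function(x, ...) standardGeneric("datasetLabel"))

#' @rdname coexmod-generics
#' @export
setGeneric("traitDesign", function(x, ...) standardGeneric("traitDesign"))

#' @rdname coexmod-generics
#' @export
setGeneric("moduleAssignments", function(x, ...)
  standardGeneric("moduleAssignments"))

#' @rdname coexmod-generics
#' @export
setGeneric("eigengenes", function(x, ...) standardGeneric("eigengenes"))

#' @rdname coexmod-generics
#' @export
setGeneric("moduleKME", function(x, ...) standardGeneric("moduleKME"))

#' @rdname coexmod-generics
#' @export
setGeneric("moduleSizes", function(x, ...) standardGeneric("moduleSizes"))

#' @rdname coexmod-generics
#' @export
setGeneric("moduleGenes", function(x, ...) standardGeneric("moduleGenes"))

#' @rdname coexmod-generics
#' @export
setGeneric("nModules", function(x, ...) standardGeneric("nModules"))

#' @rdname coexmod-generics
#' @export
setGeneric("geneSets", function(x, ...) standardGeneric("geneSets"))

#' @rdname coexmod-generics
#' @export
setGeneric("setNamesOf", function(x, ...) standardGeneric("setNamesOf"))

#' @rdname coexmod-generics
#' @export
setGeneric("resultTable", function(x, ...) standardGeneric("resultTable"))

#' @rdname coexmod-generics
#' @export
setGeneric("chosenPower", function(x, ...) standardGeneric("chosenPower"))
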