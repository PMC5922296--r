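#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- expression

#' ExpressionDataset: log2 expression with sample annotation
#'
#' Container for a normalized, log2-scale gene-by-sample expression matrix.
#' Extends \linkS4class{SummarizedExperiment}; the single assay is named
#' \code{"log2expr"} and the sample trait design (tissue, condition, ...)
#' lives in \code{colData}. All values must be finite: missing values are
#' resolved at load time (see \code{\link{readExpressionTsv}}) so that the
#' Pearson-correlation machinery downstream never needs missing-data masks.
#'
#' @slot datasetLabel single string naming the dataset (e.g. a study arm).
#'
#' @seealso \code{\link{readExpressionTsv}}, \code{\link{filterGenes}}
#' @export
setClass("ExpressionDataset",
  contains = "SummarizedExperiment",
  slots = c(datasetLabel = "character")
)

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (length(object@datasetLabel) != 1L)
    msg <- c(msg, "datasetLabel must be a single string")
  if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2expr' is required")
  g <- rownames(object); s <- colnames(object)
  if (is.null(g) || anyDuplicated(g) || any(!nzchar(g)))
    msg <- c(msg, "gene ids must be unique, non-empty strings")
  if (is.null(s) || anyDuplicated(s) || any(!nzchar(s)))
    msg <- c(msg, "sample ids must be unique, non-empty strings")
  if (length(msg) == 0L) {
    v <- SummarizedExperiment::assay(object, "log2expr")
    if (!is.numeric(v) || any(!is.finite(v)))
      msg <- c(msg, "expression values must all be finite numbers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric gene x sample matrix of log2 expression.
#' @param geneIds,sampleIds identifier vectors; default taken from dimnames.
#' @param datasetLabel label for the dataset.
#' @param traits optional trait design \code{data.frame}
#'   (see \code{\link{readTraitsTsv}}) stored in \code{colData}.
#' @return An \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ExpressionDataset(m, datasetLabel = "demo")
#' @export
ExpressionDataset <- function(values, geneIds = rownames(values),
                              sampleIds = colnames(values),
                              datasetLabel = "dataset", traits = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- geneIds
  colnames(values) <- sampleIds
  cd <- if (is.null(traits)) {
    S4Vectors::DataFrame(row.names = sampleIds)
  } else {
    traits <- validateTraitDesign(traits, sampleIds)
    S4Vectors::DataFrame(traits[match(sampleIds, traits$sample_id), ,
                                drop = FALSE],
                         row.names = sampleIds)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = values), colData = cd)
  new("ExpressionDataset", se, datasetLabel = as.character(datasetLabel))
}

#' @rdname coexmod-generics
#' @export
setMethod("exprValues", "ExpressionDataset", function(x, ...)
  SummarizedExperiment::assay(x, "log2expr"))

#' @rdname coexmod-generics
#' @export
setMethod("geneIds", "ExpressionDataset", function(x, ...) rownames(x))

#' @rdname coexmod-generics
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x, ...) colnames(x))

#' @rdname coexmod-generics
#' @export
setMethod("datasetLabel", "ExpressionDataset", function(x, ...)
  x@datasetLabel)

#' @rdname coexmod-generics
#' @export
setMethod("traitDesign", "ExpressionDataset", function(x, ...) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (!nrow(cd) || !"tissue" %in% names(cd))
    stop("no trait design attached; see attachTraits()/readTraitsTsv()")
  cd
})

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset '", object@datasetLabel, "': ",
      nrow(object), " genes x ", ncol(object), " samples\n", sep = "")
  if ("tissue" %in% names(SummarizedExperiment::colData(object))) {
    cd <- SummarizedExperiment::colData(object)
    cat("  tissues: ", paste(unique(cd$tissue), collapse = ", "), "\n",
        "  conditions: ", paste(unique(cd$condition), collapse = ", "),
        "\n", sep = "")
  }
})

# ----------------------------------------------------------------- gene sets

#' GeneSetCollection: named gene sets (GMT-backed)
#'
#' @slot sets named list of unique character vectors (no empty sets).
#' @slot descriptions named character vector, parallel to \code{sets}.
#' @seealso \code{\link{readGmt}}, \code{\link{writeGmt}}
#' @export
setClass("GeneSetList",
  slots = c(sets = "list", descriptions = "character"))

setValidity("GeneSetList", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "set names must be unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty gene sets are not allowed")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "gene sets must be deduplicated")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must parallel sets")
  if (length(msg)) msg else TRUE
})

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene ids (duplicates are
#'   removed; empty sets are an error).
#' @param descriptions optional character vector of set descriptions.
#' @return A \code{GeneSetList} object.
#' @export
GeneSetList <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  new("GeneSetList", sets = sets,
      descriptions = setNames(as.character(descriptions), names(sets)))
}

#' @rdname coexmod-generics
#' @export
setMethod("geneSets", "GeneSetList", function(x, ...) x@sets)

#' @rdname coexmod-generics
#' @export
setMethod("setNamesOf", "GeneSetList", function(x, ...)
  names(x@sets))

setMethod("show", "GeneSetList", function(object) {
  cat("GeneSetList with", length(object@sets), "sets; sizes",
      paste(range(lengths(object@sets)), collapse = "-"), "\n")
})

setMethod("length", "GeneSetList", function(x) length(x@sets))

# ------------------------------------------------------------------- modules

#' ModuleSet: module assignments, eigengenes and kME
#'
#' Result of \code{\link{detectModules}}. Module 0 collects unassigned
#' (background) genes; module ids 1..k are ordered by descending size and
#' displayed with the conventional "M" prefix.
#'
#' @slot assignments named integer vector, gene -> module id (0 unassigned).
#' @slot eigengenes module x sample matrix; each row is the first principal
#'   component of the module's standardized expression, mean 0 and unit
#'   variance, sign-oriented so the mean member kME is positive.
#' @slot kme,kmeP,kmeQ gene x module matrices of Pearson correlation with
#'   the eigengenes, two-sided p, and BH q (adjusted within module).
#' @slot moduleSizes named integer vector (modules > 0).
#' @slot parameters list of the network/cut parameters used.
#' @export
setClass("ModuleSet",
  slots = c(assignments = "integer", eigengenes = "matrix",
            kme = "matrix", kmeP = "matrix", kmeQ = "matrix",
            moduleSizes = "integer", parameters = "list"))

setValidity("ModuleSet", function(object) {
  msg <- character()
  a <- object@assignments
  if (is.null(names(a))) msg <- c(msg, "assignments must be named by gene")
  k <- nrow(object@eigengenes)
  if (k > 0) {
    if (!setequal(sort(unique(a[a > 0L])), seq_len(k)))
      msg <- c(msg, "module ids must be 1..k matching eigengene rows")
    v <- apply(object@eigengenes, 1L, var)
    if (any(abs(v - 1) > 1e-6))
      msg <- c(msg, "eigengenes must have unit variance")
    if (any(abs(rowMeans(object@eigengenes)) > 1e-8))
      msg <- c(msg, "eigengenes must have mean 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname coexmod-generics
#' @export
setMethod("moduleAssignments", "ModuleSet", function(x, ...) x@assignments)

#' @rdname coexmod-generics
#' @export
setMethod("eigengenes", "ModuleSet", function(x, ...) x@eigengenes)

#' @param what one of "r", "p", "q" selecting the kME statistic matrix.
#' @rdname coexmod-generics
#' @export
setMethod("moduleKME", "ModuleSet", function(x, what = c("r", "p", "q"), ...)
  switch(match.arg(what), r = x@kme, p = x@kmeP, q = x@kmeQ))

#' @rdname coexmod-generics
#' @export
setMethod("moduleSizes", "ModuleSet", function(x, ...) x@moduleSizes)

#' @param module module id (integer) or label such as "M3".
#' @rdname coexmod-generics
#' @export
setMethod("moduleGenes", "ModuleSet", function(x, module, ...) {
  m <- moduleId(x, module)
  names(x@assignments)[x@assignments == m]
})

#' @rdname coexmod-generics
#' @export
setMethod("nModules", "ModuleSet", function(x, ...)
  nrow(x@eigengenes))

setMethod("show", "ModuleSet", function(object) {
  k <- nModules(object)
  cat("ModuleSet:", k, "modules over", length(object@assignments),
      "genes (", sum(object@assignments == 0L), "unassigned )\n")
  if (k > 0) {
    sz <- object@moduleSizes
    cat("  sizes:", paste(sprintf("%s=%d", names(sz), sz),
                          collapse = " "), "\n")
  }
})

# internal: resolve "M3" / 3 to integer id
moduleId <- function(ms, module) {
  if (is.character(module)) {
    idx <- match(module, rownames(ms@eigengenes))
    if (is.na(idx)) stop("unknown module: ", module)
    return(idx)
  }
  module <- as.integer(module)
  if (module < 1L || module > nModules(ms))
    stop("unknown module: ", module)
  module
}

# -------------------------------------------------------------- scan results

#' SoftPowerScan: scale-free topology scan over candidate powers
#'
#' @slot scan data.frame with columns \code{power}, \code{r2} (scale-free
#'   fit R-squared from the log-log regression of the connectivity
#'   distribution), \code{slope} and \code{meanK}.
#' @slot chosenPower smallest candidate whose R-squared meets the threshold,
#'   else the documented default (6).
#' @slot r2Threshold the threshold used.
#' @export
setClass("SoftPowerScan",
  slots = c(scan = "data.frame", chosenPower = "integer",
            r2Threshold = "numeric"))

setValidity("SoftPowerScan", function(object) {
  r2 <- object@scan$r2
  if (length(r2) && any(r2 < -1e-9 | r2 > 1 + 1e-9, na.rm = TRUE))
    "r2 must lie in [0, 1]" else TRUE
})

#' @rdname coexmod-generics
#' @export
setMethod("chosenPower", "SoftPowerScan", function(x, ...) x@chosenPower)

#' @rdname coexmod-generics
#' @export
setMethod("resultTable", "SoftPowerScan", function(x, ...) x@scan)

setMethod("show", "SoftPowerScan", function(object) {
  cat("SoftPowerScan:", nrow(object@scan), "candidates; chosen power",
      object@chosenPower, "\n")
})

# ------------------------------------------------------------ trait mapping

#' ModuleTraitMatrix: module-by-trait correlation map
#'
#' Pearson (point-biserial) correlations of module eigengenes against 0/1
#' trait indicator columns, with two-sided p from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}}.
#'
#' @slot r,p module x trait matrices.
#' @slot nSamples number of samples the correlations are based on.
#' @export
setClass("ModuleTraitMatrix",
  slots = c(r = "matrix", p = "matrix", nSamples = "integer"))

setValidity("ModuleTraitMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@r), dim(object@p)))
    msg <- c(msg, "r and p must have identical dimensions")
  if (any(object@r < -1 - 1e-9 | object@r > 1 + 1e-9))
    msg <- c(msg, "r must lie in [-1, 1]")
  if (any(object@p <= 0 | object@p > 1))
    msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Extract -log10(p) matrix from a ModuleTraitMatrix
#' @param x a ModuleTraitMatrix.
#' @return matrix of -log10 p-values.
#' @export
negLogP <- function(x) {
  stopifnot(is(x, "ModuleTraitMatrix"))
  -log10(x@p)
}

setMethod("show", "ModuleTraitMatrix", function(object) {
  cat("ModuleTraitMatrix:", nrow(object@r), "modules x", ncol(object@r),
      "traits (n =", object@nSamples, "samples)\n")
})

#' EigengeneNetwork: pairwise eigengene correlation structure
#'
#' @slot edges data.frame (module_i, module_j, r, p), complete upper triangle.
#' @slot adjacency layout adjacency \eqn{((1+r)/2)^2} in [0,1].
#' @export
setClass("EigengeneNetwork",
  slots = c(edges = "data.frame", adjacency = "matrix"))

setMethod("show", "EigengeneNetwork", function(object) {
  cat("EigengeneNetwork:", nrow(object@adjacency), "modules,",
      nrow(object@edges), "edges\n")
})

# -------------------------------------------------------------- preservation

#' PreservationResult: permutation Z statistics for module preservation
#'
#' For each reference module, how well its density (mean intramodular
#' adjacency) and connectivity pattern (correlation of intramodular
#' connectivity, kIM, between datasets) replicate in an independent test
#' dataset, expressed as permutation Z scores against random gene sets of
#' matched size. \code{Zsummary = (Zdensity + Zconnectivity)/2}; if one
#' component is degenerate (null sd ~ 0, e.g. preservation of a dataset
#' against itself, where the connectivity correlation is identically 1),
#' Zsummary is the mean of the non-degenerate components and the module is
#' flagged.
#'
#' @slot table per-module data.frame (module, size, nShared, obsDensity,
#'   obsConnectivity, Zdensity, Zconnectivity, Zsummary, evaluable,
#'   degenerate).
#' @slot nPerm,seed permutation provenance.
#' @slot nullMoments per-module permutation means/sds.
#' @export
setClass("PreservationResult",
  slots = c(table = "data.frame", nPerm = "integer", seed = "integer",
            nullMoments = "data.frame"))

setMethod("show", "PreservationResult", function(object) {
  cat("PreservationResult:", nrow(object@table), "modules,",
      object@nPerm, "permutations\n")
})

#' @rdname coexmod-generics
#' @export
setMethod("resultTable", "PreservationResult", function(x, ...) x@table)

# --------------------------------------------------------------------- modDE

#' ModDEResult: module-level differential expression
#'
#' Per module: the kME-signed, kME-weighted consistency statistic T combining
#' per-gene signed z scores, its stratified label-permutation p, the
#' excess-DE component (count of members below \code{alpha0} with a
#' hypergeometric p), and BH q across modules per component.
#'
#' @slot table per-module data.frame (module, size, T, consistencyP,
#'   consistencyQ, excessK, excessExpected, excessP, excessQ).
#' @slot geneTable the per-gene test underlying the module statistics.
#' @slot nPerm,seed,nullMethod permutation provenance.
#' @export
setClass("ModDEResult",
  slots = c(table = "data.frame", geneTable = "data.frame",
            nPerm = "integer", seed = "integer", nullMethod = "character"))

setValidity("ModDEResult", function(object) {
  tb <- object@table
  msg <- character()
  if (nrow(tb)) {
    lo <- 1 / (object@nPerm + 1)
    if (any(tb$consistencyP < lo - 1e-12 | tb$consistencyP > 1 + 1e-12))
      msg <- c(msg, "permutation p must lie in [1/(nPerm+1), 1]")
    if (any(tb$consistencyQ < tb$consistencyP - 1e-12))
      msg <- c(msg, "q must be >= p componentwise")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModDEResult", function(object) {
  cat("ModDEResult:", nrow(object@table), "modules;",
      object@nPerm, "permutations (", object@nullMethod, ")\n")
})

#' @rdname coexmod-generics
#' @export
setMethod("resultTable", "ModDEResult", function(x, ...) x@table)

# ----------------------------------------------------------- synthetic data

#' SynthConfig: design of a synthetic multi-tissue expression dataset
#'
#' Describes the latent-factor generative model used for validation: per
#' module a single latent factor per sample
#' \eqn{f_m(s) = effect \cdot 1[trait(s)] + \delta \cdot 1[perturbed(s)] + N(0,1)}
#' and member genes \eqn{x_g(s) = \lambda_g f_m(s) + N(0,\sigma^2)};
#' background genes are pure noise. The incoherent perturbation mode instead
#' adds \eqn{\delta \lambda_g r_g} directly to gene g in perturbed samples
#' with random signs \eqn{r_g}, so the per-gene effect magnitude matches the
#' coherent mode while the direction is decoupled from the module
#' correlation structure.
#'
#' @slot nGenes,replicates,noiseSd,seed scalars.
#' @slot tissues,conditions character vectors defining the sample grid
#'   (tissues x conditions x replicates).
#' @slot modules data.frame: size, lambdaLo, lambdaHi, traitTissue,
#'   traitCondition, effect (NA trait fields = no trait link).
#' @slot perturbModule,perturbDelta,perturbMode,perturbCondition,perturbTissue
#'   perturbation design ("none", "coherent" or "incoherent"); the perturbed
#'   cell is (perturbCondition x perturbTissue), NA tissue = all tissues.
#' @slot secondDataset,preserved whether to emit an independent second
#'   dataset and, per module, whether its membership is kept (TRUE) or
#'   scrambled (FALSE) there.
#' @slot upperSecond relabel second-dataset genes to upper case (a
#'   two-species surrogate for orthology-mapped symbols).
#' @export
setClass("SynthConfig",
  slots = c(nGenes = "integer", tissues = "character",
            conditions = "character", replicates = "integer",
            modules = "data.frame",
            perturbModule = "integer", perturbDelta = "numeric",
            perturbMode = "character", perturbCondition = "character",
            perturbTissue = "character",
            secondDataset = "logical", preserved = "logical",
            upperSecond = "logical",
            noiseSd = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (sum(object@modules$size) > object@nGenes)
    msg <- c(msg, "sum of module sizes must not exceed nGenes")
  if (object@replicates < 2L) msg <- c(msg, "replicates must be >= 2")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  lam <- c(object@modules$lambdaLo, object@modules$lambdaHi)
  if (length(lam) && any(lam <= 0 | lam > 1))
    msg <- c(msg, "loadings must lie in (0, 1]")
  if (!object@perturbMode %in% c("none", "coherent", "incoherent"))
    msg <- c(msg, "perturbMode must be none/coherent/incoherent")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nGenes, "genes;",
      length(object@tissues), "tissues x",
      length(object@conditions), "conditions x",
      object@replicates, "replicates;",
      nrow(object@modules), "planted modules\n")
})

#' SyntheticTruth: ground truth of a generated dataset
#'
#' @slot membership named integer gene -> planted module (0 background).
#' @slot loadings named numeric per-gene loading.
#' @slot factors module x sample latent factor values (dataset 1).
#' @slot traitEffects data.frame (module, tissue, condition, effect).
#' @slot perturbation list: module, delta, mode, samples (perturbed sample
#'   ids), geneSigns (incoherent mode: named +/-1 per member gene).
#' @slot membership2 second-dataset membership (empty if single dataset).
#' @slot preserved logical per module.
#' @slot config the generating SynthConfig.
#' @export
setClass("SyntheticTruth",
  slots = c(membership = "integer", loadings = "numeric",
            factors = "matrix", traitEffects = "data.frame",
            perturbation = "list", membership2 = "integer",
            preserved = "logical", config = "SynthConfig"))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", max(object@membership), "planted modules over",
      length(object@membership), "genes\n")
})
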