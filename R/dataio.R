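#' @include AllClasses.R utils.R
NULL

# ------------------------------------------------------------ expression IO

#' Read a gene x sample expression TSV
#'
#' The expected layout is a header row of unique sample ids and a first
#' column of gene ids; cells hold normalized log2 expression. Duplicate gene
#' ids are collapsed to the highest-variance row (the usual array-probe
#' convention) with a message. Missing values are resolved at load time so
#' downstream code can assume complete matrices.
#'
#' @param path TSV file path.
#' @param missingPolicy "drop_gene" (default) drops genes with any missing
#'   value; "fail" raises an error naming the first offending cell.
#' @param datasetLabel label stored in the returned object.
#' @return An \linkS4class{ExpressionDataset}.
#' @seealso \code{\link{writeExpressionTsv}}
#' @export
readExpressionTsv <- function(path, missingPolicy = c("drop_gene", "fail"),
                              datasetLabel = basename(path)) {
  missingPolicy <- match.arg(missingPolicy)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L)
    stop("malformed header in ", path, ": need gene id column plus samples")
  sampleIds <- colnames(raw)[-1L]
  dup <- sampleIds[duplicated(sampleIds)]
  if (length(dup))
    stop("duplicate sample id(s) in header: ",
         paste(unique(dup), collapse = ", "))
  genes <- raw[[1L]]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, sampleIds))
  cm <- as.matrix(raw[-1L])   # read.delim already turned "NA" into NA
  bad <- is.na(vals) & !is.na(cm) & !(toupper(trimws(cm)) %in% c("NAN", ""))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at gene '", genes[idx[1L]], "', sample '",
         sampleIds[idx[2L]], "'")
  }
  if (anyNA(vals)) {
    if (missingPolicy == "fail") {
      idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", genes[idx[1L]], "', sample '",
           sampleIds[idx[2L]], "'")
    }
    keep <- rowSums(is.na(vals)) == 0L
    message("dropping ", sum(!keep), " gene(s) with missing values")
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  if (anyDuplicated(genes)) {
    v <- rowVars2(vals)
    ord <- order(-v)              # highest-variance row wins
    first <- ord[!duplicated(genes[ord])]
    message("collapsing ", length(genes) - length(first),
            " duplicate gene id row(s) by highest variance")
    first <- sort(first)          # keep original file order
    vals <- vals[first, , drop = FALSE]
    genes <- genes[first]
  }
  rownames(vals) <- genes
  ExpressionDataset(vals, datasetLabel = datasetLabel)
}

#' Write an ExpressionDataset as TSV
#'
#' @param expr an \linkS4class{ExpressionDataset}.
#' @param path output path.
#' @param idColumn name for the gene id column.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTsv <- function(expr, path, idColumn = "gene_id") {
  v <- exprValues(expr)
  df <- data.frame(check.names = FALSE,
                   setNames(list(rownames(v)), idColumn), v)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ----------------------------------------------------------------- traits IO

validateTraitDesign <- function(traits, sampleIds) {
  req <- c("sample_id", "tissue", "condition")
  miss <- setdiff(req, names(traits))
  if (length(miss))
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(traits$sample_id))
    stop("duplicate sample_id(s) in trait table: ",
         paste(unique(traits$sample_id[duplicated(traits$sample_id)]),
               collapse = ", "))
  absent <- setdiff(sampleIds, traits$sample_id)
  if (length(absent))
    stop("sample(s) in expression missing from traits: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(traits$sample_id, sampleIds)
  if (length(extra))
    stop("sample(s) in traits absent from expression: ",
         paste(extra, collapse = ", "))
  traits
}

#' Read a sample trait/design TSV matched against an expression dataset
#'
#' Requires columns \code{sample_id}, \code{tissue}, \code{condition};
#' optional \code{group} and \code{replicate}. Every expression sample must
#' appear exactly once, and vice versa; mismatches are an error listing the
#' offending ids.
#'
#' @param path TSV file path.
#' @param expr the paired \linkS4class{ExpressionDataset}.
#' @return A \code{data.frame} ordered like \code{sampleIds(expr)}.
#' @export
readTraitsTsv <- function(path, expr) {
  tr <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  tr <- validateTraitDesign(tr, sampleIds(expr))
  tr[match(sampleIds(expr), tr$sample_id), , drop = FALSE]
}

#' Write a trait design table as TSV
#' @param traits trait design data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTraitsTsv <- function(traits, path) {
  write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a trait design to an ExpressionDataset
#'
#' @param expr an \linkS4class{ExpressionDataset}.
#' @param traits trait design data.frame (validated against the samples).
#' @return The dataset with traits in \code{colData}.
#' @export
attachTraits <- function(expr, traits) {
  traits <- validateTraitDesign(traits, sampleIds(expr))
  ExpressionDataset(exprValues(expr), datasetLabel = datasetLabel(expr),
                    traits = traits)
}

# -------------------------------------------------------------------- GMT IO

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated \code{name},
#' \code{description}, members. Members are deduplicated; a line with fewer
#' than three fields (no members) is an error reporting the line number.
#'
#' @param path GMT file path.
#' @return A \linkS4class{GeneSetList}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop("GMT line ", i, ": fewer than 3 fields (empty member list?)")
    sets[[f[1L]]] <- unique(f[-(1:2)])
    descs[f[1L]] <- f[2L]
  }
  GeneSetList(sets, descs)
}

#' Write gene sets to a GMT file
#'
#' @param collection a \linkS4class{GeneSetList}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "GeneSetList"))
  lines <- vapply(names(collection@sets), function(nm) {
    paste(c(nm, if (nzchar(collection@descriptions[[nm]]))
      collection@descriptions[[nm]] else "na",
      collection@sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ------------------------------------------------------------ gene filtering

#' Filter genes by exclusion list and variance
#'
#' Applies the tissue-specific gene subtraction step used before sample-level
#' ordination: genes on the exclusion list are removed first, then (if
#' requested) only the \code{topK} most variable genes are kept. The order
#' of the remaining genes is preserved, so the operation is idempotent for a
#' fixed exclusion list and \code{topK}.
#'
#' @param expr an \linkS4class{ExpressionDataset}.
#' @param exclude character vector of gene ids to remove (may be empty).
#' @param topK keep only this many highest-variance genes (NULL = keep all).
#' @return A filtered \linkS4class{ExpressionDataset}.
#' @export
filterGenes <- function(expr, exclude = character(), topK = NULL) {
  v <- exprValues(expr)
  keep <- !(rownames(v) %in% exclude)
  v <- v[keep, , drop = FALSE]
  if (!is.null(topK)) {
    topK <- as.integer(topK)
    if (topK < 2L) stop("topK must be >= 2")
    if (topK < nrow(v)) {
      vars <- rowVars2(v)
      sel <- sort(order(-vars)[seq_len(topK)])  # preserve original order
      v <- v[sel, , drop = FALSE]
    }
  }
  if (nrow(v) < 2L)
    stop("fewer than 2 genes remain after filtering")
  out <- ExpressionDataset(v, datasetLabel = datasetLabel(expr))
  cd <- SummarizedExperiment::colData(expr)
  if (ncol(cd)) SummarizedExperiment::colData(out) <- cd
  out
}

# ------------------------------------------------------------ symbol mapping

#' Map gene identifiers through an orthology/symbol table
#'
#' Cross-species comparisons (e.g. mouse modules against a human ranked
#' list) need an explicit two-column mapping. Unmapped genes are dropped
#' with a message stating the count. As a documented convenience, with no
#' table the mouse-style capitalization fallback (\code{Gzmb -> GZMB}) is
#' applied.
#'
#' @param x a \linkS4class{GeneSetList} or \linkS4class{ExpressionDataset}.
#' @param mappingTable data.frame with columns \code{from}, \code{to}
#'   (or first two columns used as such); NULL enables the upper-case
#'   fallback.
#' @return Object of the same class with mapped identifiers; duplicates
#'   after mapping are collapsed (expression: highest variance; sets:
#'   deduplicated). An empty result is an error.
#' @export
mapGeneSymbols <- function(x, mappingTable = NULL) {
  mapFun <- if (is.null(mappingTable)) {
    toupper
  } else {
    if (ncol(mappingTable) < 2L)
      stop("mappingTable needs two columns (from, to)")
    from <- as.character(mappingTable[[1L]])
    to <- as.character(mappingTable[[2L]])
    function(g) unname(setNames(to, from)[g])
  }
  if (is(x, "GeneSetList")) {
    dropped <- 0L
    sets <- lapply(x@sets, function(s) {
      m <- mapFun(s)
      dropped <<- dropped + sum(is.na(m))
      unique(m[!is.na(m)])
    })
    keep <- lengths(sets) > 0L
    if (dropped) message("dropped ", dropped, " unmapped gene(s)")
    if (!any(keep)) stop("no gene set survived mapping")
    GeneSetList(sets[keep], x@descriptions[keep])
  } else if (is(x, "ExpressionDataset")) {
    v <- exprValues(x)
    m <- mapFun(rownames(v))
    drop <- is.na(m)
    if (any(drop)) message("dropped ", sum(drop), " unmapped gene(s)")
    v <- v[!drop, , drop = FALSE]
    m <- m[!drop]
    if (!nrow(v)) stop("no gene survived mapping")
    if (anyDuplicated(m)) {
      vars <- rowVars2(v)
      ord <- order(-vars)
      first <- sort(ord[!duplicated(m[ord])])
      v <- v[first, , drop = FALSE]
      m <- m[first]
    }
    rownames(v) <- m
    out <- ExpressionDataset(v, datasetLabel = datasetLabel(x))
    cd <- SummarizedExperiment::colData(x)
    if (ncol(cd)) SummarizedExperiment::colData(out) <- cd
    out
  } else stop("unsupported type for mapGeneSymbols: ", class(x)[1L])
}
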