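#' @include AllClasses.R netbuild.R
NULL

# density / connectivity statistics of one gene set in (ref, test) data
presStats <- function(genes, refV, testV, power, mode) {
  m <- length(genes)
  aTest <- adjacencyMatrix(cor(t(testV[genes, , drop = FALSE])), power, mode)
  density <- sum(aTest) / (m * (m - 1))
  aRef <- adjacencyMatrix(cor(t(refV[genes, , drop = FALSE])), power, mode)
  kRef <- rowSums(aRef); kTest <- rowSums(aTest)
  connectivity <- if (sd(kRef) == 0 || sd(kTest) == 0) NA_real_
                  else cor(kRef, kTest)
  c(density = density, connectivity = connectivity)
}

#' Cross-dataset module preservation (permutation Z statistics)
#'
#' Quantifies whether each reference module retains its topology in an
#' independent test dataset. Two observed statistics per module: density
#' (mean off-diagonal soft-threshold adjacency among the module genes in the
#' test data) and connectivity (Pearson correlation of the intramodular
#' connectivity vectors kIM computed in reference vs test over the shared
#' module genes). The null re-evaluates both on \code{nPerm} random gene
#' sets of identical size drawn from the genes shared by both datasets,
#' excluding the module under test (so module signal cannot leak into the
#' null); \eqn{Z = (obs - mean_{null})/sd_{null}} and
#' \eqn{Z_{summary} = (Z_{density} + Z_{connectivity})/2}.
#' Modules whose gene overlap with the test data falls below
#' \code{overlapFloor} of their size are flagged not evaluable; a null sd
#' of ~0 flags the component degenerate and Zsummary falls back to the
#' remaining component.
#'
#' @param refExpr,testExpr \linkS4class{ExpressionDataset}s (or matrices).
#' @param refModules \linkS4class{ModuleSet} defined on the reference data.
#' @param power,mode adjacency parameters applied identically to both
#'   datasets.
#' @param nPerm number of permutations (default 200).
#' @param seed RNG seed; fixed seed gives bitwise-identical draws.
#' @param overlapFloor minimum shared fraction of a module (default 0.5).
#' @return A \linkS4class{PreservationResult}.
#' @seealso \code{\link{classifyPreservation}}
#' @export
modulePreservation <- function(refExpr, testExpr, refModules, power = 6L,
                               mode = c("signed_hybrid", "unsigned"),
                               nPerm = 200L, seed = NULL,
                               overlapFloor = 0.5) {
  mode <- match.arg(mode)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  refV <- if (is(refExpr, "ExpressionDataset")) exprValues(refExpr)
          else as.matrix(refExpr)
  testV <- if (is(testExpr, "ExpressionDataset")) exprValues(testExpr)
           else as.matrix(testExpr)
  shared <- intersect(rownames(refV), rownames(testV))
  assign <- moduleAssignments(refModules)
  ids <- sort(unique(assign[assign > 0L]))
  rows <- list(); moments <- list()
  withSeed(seed, {
    for (m in ids) {
      genes <- names(assign)[assign == m]
      sharedM <- intersect(genes, shared)
      lab <- paste0("M", m)
      if (length(sharedM) < overlapFloor * length(genes) ||
          length(sharedM) < 3L) {
        rows[[lab]] <- data.frame(module = lab, size = length(genes),
          nShared = length(sharedM), obsDensity = NA, obsConnectivity = NA,
          Zdensity = NA, Zconnectivity = NA, Zsummary = NA,
          evaluable = FALSE, degenerate = FALSE)
        next
      }
      obs <- presStats(sharedM, refV, testV, power, mode)
      pool <- setdiff(shared, genes)
      nullMat <- vapply(seq_len(nPerm), function(i) {
        presStats(sample(pool, length(sharedM)), refV, testV, power, mode)
      }, numeric(2))
      mu <- rowMeans(nullMat, na.rm = TRUE)
      sdv <- apply(nullMat, 1L, sd, na.rm = TRUE)
      degenerate <- sdv < 1e-12 | !is.finite(sdv)
      z <- ifelse(degenerate, NA_real_, (obs - mu) / sdv)
      zs <- mean(z, na.rm = TRUE)
      rows[[lab]] <- data.frame(module = lab, size = length(genes),
        nShared = length(sharedM), obsDensity = obs[["density"]],
        obsConnectivity = obs[["connectivity"]],
        Zdensity = z[["density"]], Zconnectivity = z[["connectivity"]],
        Zsummary = if (is.nan(zs)) NA_real_ else zs,
        evaluable = TRUE, degenerate = any(degenerate))
      moments[[lab]] <- data.frame(module = lab,
        meanDensity = mu[["density"]], sdDensity = sdv[["density"]],
        meanConnectivity = mu[["connectivity"]],
        sdConnectivity = sdv[["connectivity"]])
    }
  })
  new("PreservationResult",
      table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      nPerm = as.integer(nPerm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nullMoments = if (length(moments))
        do.call(rbind, c(moments, list(make.row.names = FALSE)))
      else data.frame())
}

#' Label modules by preservation strength
#'
#' Applies the conventional Zsummary thresholds: below 2 evidence of
#' preservation is absent; 2-10 is weak to moderate; 10 and above (the
#' stringent cutoff) is strong.
#'
#' @param result a \linkS4class{PreservationResult}.
#' @param weak,strong thresholds (defaults 2 and 10; \code{strong} is
#'   inclusive).
#' @return named character vector of labels
#'   (\code{not_preserved}, \code{weak_to_moderate}, \code{strong},
#'   \code{not_evaluable}).
#' @export
classifyPreservation <- function(result, weak = 2.0, strong = 10.0) {
  stopifnot(is(result, "PreservationResult"))
  tb <- result@table
  lab <- ifelse(!tb$evaluable | is.na(tb$Zsummary), "not_evaluable",
         ifelse(tb$Zsummary < weak, "not_preserved",
         ifelse(tb$Zsummary < strong, "weak_to_moderate", "strong")))
  setNames(lab, tb$module)
}
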