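#' @include AllClasses.R modules.R
NULL

#' Build 0/1 trait indicator columns from a sample design
#'
#' One indicator column per tissue (\code{tissue_<t>}), per condition
#' (\code{condition_<c>}), and per configured higher-level group
#' (\code{group_<name>}, e.g. secondary lymphoid organs vs target organs).
#'
#' @param design trait design data.frame (sample_id, tissue, condition).
#' @param grouping optional named list of tissue groups, e.g.
#'   \code{list(SLO = c("spleen", "pLN"))}; referencing an unknown tissue
#'   is an error.
#' @return sample x trait 0/1 matrix with rownames \code{sample_id}.
#' @export
binaryTraits <- function(design, grouping = list()) {
  stopifnot(all(c("sample_id", "tissue", "condition") %in% names(design)))
  tis <- unique(design$tissue)
  con <- unique(design$condition)
  cols <- list()
  for (t in tis) cols[[paste0("tissue_", t)]] <- as.integer(design$tissue == t)
  for (c0 in con)
    cols[[paste0("condition_", c0)]] <- as.integer(design$condition == c0)
  for (g in names(grouping)) {
    unknown <- setdiff(grouping[[g]], tis)
    if (length(unknown))
      stop("group '", g, "' references unknown tissue(s): ",
           paste(unknown, collapse = ", "))
    cols[[paste0("group_", g)]] <-
      as.integer(design$tissue %in% grouping[[g]])
  }
  out <- do.call(cbind, cols)
  rownames(out) <- design$sample_id
  out
}

#' Module-trait correlation map
#'
#' Pearson (point-biserial) correlation of each module eigengene with each
#' 0/1 trait indicator, with two-sided p from the t transform. A constant
#' trait column yields r = 0, p = 1 with a warning.
#'
#' @param eigengenes module x sample matrix
#'   (\code{\link{moduleEigengenes}} or a \linkS4class{ModuleSet} via
#'   \code{eigengenes()}).
#' @param traits sample x trait indicator matrix from
#'   \code{\link{binaryTraits}} (rows matched to eigengene columns).
#' @return A \linkS4class{ModuleTraitMatrix}.
#' @export
moduleTraitMatrix <- function(eigengenes, traits) {
  if (is(eigengenes, "ModuleSet")) eigengenes <- eigengenes(eigengenes)
  traits <- as.matrix(traits)
  if (!is.null(rownames(traits)) && !is.null(colnames(eigengenes)))
    traits <- traits[colnames(eigengenes), , drop = FALSE]
  n <- ncol(eigengenes)
  if (n < 3L) stop("need at least 3 samples")
  constant <- apply(traits, 2L, function(x) var(x) == 0)
  if (any(constant))
    warning("constant trait column(s): ",
            paste(colnames(traits)[constant], collapse = ", "),
            " (reported as r = 0, p = 1)")
  r <- matrix(0, nrow(eigengenes), ncol(traits),
              dimnames = list(rownames(eigengenes), colnames(traits)))
  ok <- !constant
  if (any(ok)) r[, ok] <- cor(t(eigengenes), traits[, ok, drop = FALSE])
  p <- matrix(1, nrow(r), ncol(r), dimnames = dimnames(r))
  p[, ok] <- corPvalue(r[, ok, drop = FALSE], n)
  new("ModuleTraitMatrix", r = r, p = p, nSamples = as.integer(n))
}

#' Rank modules by association with one trait
#'
#' Returns the modules passing the \eqn{-\log_{10}(p)} cutoff (default 2,
#' i.e. p < 0.01), split by correlation sign and ordered by |r| descending —
#' the convention used to nominate the most site-correlated modules.
#'
#' @param mtm a \linkS4class{ModuleTraitMatrix}.
#' @param trait trait column name.
#' @param neglogpCutoff cutoff on -log10(p) (default 2).
#' @return list with character vectors \code{positive} and \code{negative}.
#' @export
rankModulesByTrait <- function(mtm, trait, neglogpCutoff = 2) {
  stopifnot(is(mtm, "ModuleTraitMatrix"))
  if (!trait %in% colnames(mtm@r)) stop("unknown trait: ", trait)
  r <- mtm@r[, trait]; p <- mtm@p[, trait]
  pass <- -log10(p) > neglogpCutoff
  pos <- names(which(pass & r > 0)); neg <- names(which(pass & r < 0))
  list(positive = pos[order(-abs(r[pos]))],
       negative = neg[order(-abs(r[neg]))])
}

#' Classify modules by their spatial association pattern
#'
#' Labels each module from the pattern of significant positive trait
#' correlations across two tissue compartments (e.g. secondary lymphoid
#' organs vs GVHD target organs): exactly one tissue ->
#' \code{tissue_specific}; several tissues within one compartment ->
#' \code{group_selective}; significant tissues in both compartments ->
#' \code{bridging}; none -> \code{unassociated}. Only positive correlations
#' drive the labels; negative associations are left to the caller.
#'
#' @param mtm a \linkS4class{ModuleTraitMatrix}.
#' @param groupTraits named list of two character vectors of tissue trait
#'   columns, e.g. \code{list(SLO = ..., target = ...)}.
#' @param alpha significance level on the per-cell p (default 0.01).
#' @return named character vector of labels per module.
#' @export
classifyModules <- function(mtm, groupTraits, alpha = 0.01) {
  stopifnot(is(mtm, "ModuleTraitMatrix"), length(groupTraits) == 2L)
  allTraits <- unlist(groupTraits, use.names = FALSE)
  unknown <- setdiff(allTraits, colnames(mtm@r))
  if (length(unknown))
    stop("unknown trait name(s): ", paste(unknown, collapse = ", "))
  vapply(rownames(mtm@r), function(m) {
    sig <- allTraits[mtm@p[m, allTraits] < alpha & mtm@r[m, allTraits] > 0]
    inG1 <- sum(sig %in% groupTraits[[1L]])
    inG2 <- sum(sig %in% groupTraits[[2L]])
    if (inG1 > 0 && inG2 > 0) "bridging"
    else if (inG1 + inG2 == 1L) "tissue_specific"
    else if (inG1 + inG2 > 1L) "group_selective"
    else "unassociated"
  }, character(1))
}

#' Eigengene correlation network
#'
#' Pairwise Pearson correlation between module eigengenes, with p-values and
#' the layout adjacency \eqn{((1 + r)/2)^2} used to draw intermodular
#' connectivity maps (thicker edges = stronger correlation).
#'
#' @param eigengenes module x sample matrix or \linkS4class{ModuleSet}.
#' @return An \linkS4class{EigengeneNetwork}.
#' @export
eigengeneNetwork <- function(eigengenes) {
  if (is(eigengenes, "ModuleSet")) eigengenes <- eigengenes(eigengenes)
  if (nrow(eigengenes) < 2L) stop("need at least 2 modules")
  r <- cor(t(eigengenes))
  p <- matrix(corPvalue(r, ncol(eigengenes)), nrow(r), ncol(r),
              dimnames = dimnames(r))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(module_i = rownames(r)[idx[, 1L]],
                      module_j = rownames(r)[idx[, 2L]],
                      r = r[idx], p = p[idx])
  adj <- ((1 + r) / 2)^2
  diag(adj) <- 1
  new("EigengeneNetwork", edges = edges, adjacency = adj)
}

#' Classical (Torgerson) MDS map of samples
#'
#' Double-centers the squared inter-sample distance matrix and embeds the
#' samples on the top eigenvectors scaled by the square root of their
#' eigenvalues. Distances are Euclidean over the \code{topK} most variable
#' genes by default (correlation distance 1 - r available). Negative
#' eigenvalues (non-Euclidean input) are clamped to zero with a warning
#' when they dominate.
#'
#' @param expr an \linkS4class{ExpressionDataset} or matrix.
#' @param nDims embedding dimension (default 2).
#' @param distance "euclidean_topvar" (default) or "correlation".
#' @param topK number of top-variance genes used (default 500).
#' @return sample x nDims coordinate matrix with attribute
#'   \code{"eigenvalues"}.
#' @export
classicalMds <- function(expr, nDims = 2L,
                         distance = c("euclidean_topvar", "correlation"),
                         topK = 500L) {
  distance <- match.arg(distance)
  v <- if (is(expr, "ExpressionDataset")) exprValues(expr) else as.matrix(expr)
  if (ncol(v) < nDims + 1L) stop("need at least nDims + 1 samples")
  if (distance == "euclidean_topvar") {
    if (topK < nrow(v)) {
      vars <- rowVars2(v)
      v <- v[sort(order(-vars)[seq_len(topK)]), , drop = FALSE]
    }
    d <- dist(t(v))
  } else {
    d <- as.dist(1 - cor(v))
  }
  fit <- cmdscale(d, k = nDims, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig))))
    warning("negative eigenvalues clamped to 0 (non-Euclidean distances)")
  coords <- fit$points
  rownames(coords) <- colnames(v)
  attr(coords, "eigenvalues") <- fit$eig
  coords
}
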