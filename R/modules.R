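#' @include AllClasses.R netbuild.R
NULL

# First principal component of a member x sample matrix, as a unit-variance,
# mean-zero sample profile. Orientation: mean member correlation positive;
# an exactly balanced module is oriented by the sign of the loading of the
# lexicographically first member gene.
eigengeneOf <- function(v) {
  if (nrow(v) == 1L) return(drop(scaleRows(v)))
  x <- scaleRows(v)
  e <- eigen(crossprod(x), symmetric = TRUE)
  me <- e$vectors[, 1L]
  me <- me / sd(me)
  cr <- as.numeric(cor(t(v), me))
  msign <- mean(cr)
  if (abs(msign) > 1e-10) {
    if (msign < 0) me <- -me
  } else {
    first <- order(rownames(v))[1L]
    if (cr[first] < 0) me <- -me
  }
  me
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized member expression, i.e. the single sample profile explaining
#' the most member variance. Rows are scaled to mean 0 and unit variance and
#' sign-oriented so that the mean correlation with the members (mean kME) is
#' positive. A single-gene module's eigengene is that gene standardized.
#'
#' @param expr an \linkS4class{ExpressionDataset} or gene x sample matrix.
#' @param assignments named integer vector gene -> module id (0 ignored).
#' @return module x sample matrix with rows named \code{M<id>}.
#' @export
moduleEigengenes <- function(expr, assignments) {
  v <- if (is(expr, "ExpressionDataset")) exprValues(expr) else as.matrix(expr)
  assignments <- assignments[names(assignments) %in% rownames(v)]
  ids <- sort(unique(assignments[assignments > 0L]))
  me <- matrix(0, length(ids), ncol(v),
               dimnames = list(paste0("M", ids), colnames(v)))
  for (i in seq_along(ids)) {
    g <- names(assignments)[assignments == ids[i]]
    me[i, ] <- eigengeneOf(v[g, , drop = FALSE])
  }
  me
}

#' Module membership (kME) of every gene against every eigengene
#'
#' Pearson correlation of each gene's profile with each module eigengene,
#' with two-sided p from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} and BH-adjusted q
#' computed within module across genes (matching per-module FDR coloring of
#' hub subnetwork displays).
#'
#' @param expr an \linkS4class{ExpressionDataset} or gene x sample matrix.
#' @param eigengenes module x sample matrix from
#'   \code{\link{moduleEigengenes}}.
#' @return list with gene x module matrices \code{r}, \code{p}, \code{q}.
#' @export
kme <- function(expr, eigengenes) {
  v <- if (is(expr, "ExpressionDataset")) exprValues(expr) else as.matrix(expr)
  n <- ncol(v)
  if (n <= 2L) stop("kME needs more than 2 samples")
  r <- cor(t(v), t(eigengenes))
  p <- matrix(corPvalue(r, n), nrow(r), ncol(r), dimnames = dimnames(r))
  q <- apply(p, 2L, p.adjust, method = "BH")
  q <- matrix(q, nrow(p), ncol(p), dimnames = dimnames(p))
  list(r = r, p = p, q = q)
}

# Recursive (dynamic hybrid-style) branch decomposition of an average-linkage
# tree on 1 - TOM. Above cutHeight branches are always followed; below it a
# branch is split only when both children could stand as modules (>= minSize)
# and their eigengene dissimilarity exceeds mergeThreshold (so the split
# would survive merging). Undersized siblings are shed as strays and later
# reassigned by kME.
cutCandidates <- function(h, v, minSize, cutHeight, mergeThreshold) {
  n <- nrow(v)
  nnode <- nrow(h$merge)
  leaves <- vector("list", nnode)
  for (i in seq_len(nnode)) {
    ch <- h$merge[i, ]
    leaves[[i]] <- c(if (ch[1L] < 0) -ch[1L] else leaves[[ch[1L]]],
                     if (ch[2L] < 0) -ch[2L] else leaves[[ch[2L]]])
  }
  nodeSize <- function(x) if (x < 0) 1L else length(leaves[[x]])
  nodeLeaves <- function(x) if (x < 0) -x else leaves[[x]]
  clusters <- list()
  strays <- integer()
  stack <- nnode
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (node < 0 || nodeSize(node) < minSize) {
      strays <- c(strays, nodeLeaves(node)); next
    }
    ch <- h$merge[node, ]
    s1 <- nodeSize(ch[1L]); s2 <- nodeSize(ch[2L])
    if (h$height[node] > cutHeight) {        # static cut: always descend
      stack <- c(stack, ch[1L], ch[2L]); next
    }
    if (nodeSize(node) < 2L * minSize) {
      clusters[[length(clusters) + 1L]] <- leaves[[node]]; next
    }
    if (min(s1, s2) >= minSize) {
      me1 <- eigengeneOf(v[nodeLeaves(ch[1L]), , drop = FALSE])
      me2 <- eigengeneOf(v[nodeLeaves(ch[2L]), , drop = FALSE])
      if (1 - cor(me1, me2) > mergeThreshold) {
        stack <- c(stack, ch[1L], ch[2L])
      } else {
        clusters[[length(clusters) + 1L]] <- leaves[[node]]
      }
    } else {
      big <- ch[which.max(c(s1, s2))]
      small <- ch[which.min(c(s1, s2))]
      strays <- c(strays, nodeLeaves(small))
      stack <- c(stack, big)
    }
  }
  list(clusters = clusters, strays = strays)
}

#' Detect coexpression modules
#'
#' Full module-discovery pass: Pearson correlation, soft-thresholded
#' adjacency, topological overlap, average-linkage hierarchical clustering of
#' 1 - TOM, an adaptive branch cut, a kME quality gate, PAM-like kME
#' reassignment of stray genes, and iterative merging of modules whose
#' eigengenes correlate above \code{1 - mergeThreshold}. Genes in clusters
#' below \code{minSize} (or failing the membership threshold) are assigned
#' to module 0. Module ids are ordered by descending size. The procedure is
#' deterministic: \code{seed} is recorded for provenance only.
#'
#' @param expr filtered \linkS4class{ExpressionDataset} or matrix.
#' @param power soft power (integer) or \code{"auto"} to scan via
#'   \code{\link{pickSoftPower}}.
#' @param mode network mode, see \code{\link{adjacencyMatrix}}.
#' @param minSize minimum module size (default 30).
#' @param cutHeight static dendrogram cut height on 1 - TOM (default 0.995).
#' @param deepSplit 0..4; controls the kME cluster-quality gate
#'   (\code{0.5 - 0.1 * deepSplit}): larger values admit looser clusters.
#' @param mergeThreshold eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param kmeCut minimum kME for final gene-module membership (default 0.4).
#' @param seed recorded in the parameters (no randomness is used).
#' @return A \linkS4class{ModuleSet}.
#' @export
detectModules <- function(expr, power = 6L,
                          mode = c("signed_hybrid", "unsigned"),
                          minSize = 30L, cutHeight = 0.995,
                          deepSplit = 2L, mergeThreshold = 0.25,
                          kmeCut = 0.4, seed = NULL) {
  mode <- match.arg(mode)
  v <- if (is(expr, "ExpressionDataset")) exprValues(expr) else as.matrix(expr)
  params <- list(power = power, mode = mode, minSize = minSize,
                 cutHeight = cutHeight, deepSplit = deepSplit,
                 mergeThreshold = mergeThreshold, kmeCut = kmeCut,
                 seed = seed)
  emptyResult <- function() {
    a <- setNames(integer(nrow(v)), rownames(v))
    new("ModuleSet", assignments = a,
        eigengenes = matrix(0, 0, ncol(v),
                            dimnames = list(NULL, colnames(v))),
        kme = matrix(0, nrow(v), 0, dimnames = list(rownames(v), NULL)),
        kmeP = matrix(0, nrow(v), 0, dimnames = list(rownames(v), NULL)),
        kmeQ = matrix(0, nrow(v), 0, dimnames = list(rownames(v), NULL)),
        moduleSizes = integer(), parameters = params)
  }
  if (nrow(v) < minSize) {
    warning("fewer genes than minSize: all genes unassigned")
    return(emptyResult())
  }
  if (identical(power, "auto"))
    power <- chosenPower(pickSoftPower(v, mode = mode))
  params$power <- power
  corr <- correlationMatrix(v)
  adj <- adjacencyMatrix(corr, power, mode)
  tom <- topologicalOverlap(adj)
  h <- hclust(as.dist(1 - tom), method = "average")
  cand <- cutCandidates(h, v, minSize, cutHeight, mergeThreshold)

  kmeGate <- max(0.1, 0.5 - 0.1 * deepSplit)
  keep <- list()
  for (cl in cand$clusters) {
    sub <- v[cl, , drop = FALSE]
    me <- eigengeneOf(sub)
    if (mean(cor(t(sub), me)) >= kmeGate)
      keep[[length(keep) + 1L]] <- cl
  }
  if (!length(keep)) return(emptyResult())

  # PAM-like stage: every gene joins its best-kME module if the membership
  # clears kmeCut, else module 0; undersized modules then dissolve.
  mes <- t(vapply(keep, function(cl)
    eigengeneOf(v[cl, , drop = FALSE]), numeric(ncol(v))))
  km <- cor(t(v), t(mes))
  best <- max.col(km, ties.method = "first")
  bestVal <- km[cbind(seq_len(nrow(v)), best)]
  assign <- ifelse(bestVal >= kmeCut, best, 0L)
  sz <- tabulate(assign, nbins = length(keep))
  for (m in which(sz < minSize)) assign[assign == m] <- 0L
  if (!any(assign > 0L)) return(emptyResult())

  # iterative eigengene merging
  groups <- split(seq_len(nrow(v)), assign)
  groups <- groups[names(groups) != "0"]
  repeat {
    if (length(groups) < 2L) break
    mes <- t(vapply(groups, function(g)
      eigengeneOf(v[g, , drop = FALSE]), numeric(ncol(v))))
    cc <- cor(t(mes)); diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (cc[top[1L], top[2L]] <= 1 - mergeThreshold) break
    i <- min(top); j <- max(top)
    groups[[i]] <- c(groups[[i]], groups[[j]])
    groups[[j]] <- NULL
  }

  # renumber by descending size; final eigengenes and kME tables
  ord <- order(-lengths(groups))
  groups <- groups[ord]
  assignments <- setNames(integer(nrow(v)), rownames(v))
  for (i in seq_along(groups)) assignments[groups[[i]]] <- i
  finalizeModuleSet(v, assignments, params)
}

# Build a ModuleSet from a finished assignment vector.
finalizeModuleSet <- function(v, assignments, params) {
  me <- moduleEigengenes(v, assignments)
  kk <- kme(v, me)
  ids <- sort(unique(assignments[assignments > 0L]))
  sz <- vapply(ids, function(m) sum(assignments == m), 0L)
  names(sz) <- paste0("M", ids)
  new("ModuleSet", assignments = assignments, eigengenes = me,
      kme = kk$r, kmeP = kk$p, kmeQ = kk$q,
      moduleSizes = sz, parameters = params)
}

#' Assemble a ModuleSet from known assignments
#'
#' Computes eigengenes and kME for an externally supplied gene -> module
#' labeling (e.g. planted truth, or assignments reloaded from disk).
#'
#' @param expr an \linkS4class{ExpressionDataset} or matrix.
#' @param assignments named integer vector gene -> module id (0 unassigned).
#' @param parameters optional provenance list.
#' @return A \linkS4class{ModuleSet}.
#' @export
moduleSetFromAssignments <- function(expr, assignments,
                                     parameters = list()) {
  v <- if (is(expr, "ExpressionDataset")) exprValues(expr) else as.matrix(expr)
  stopifnot(!is.null(names(assignments)))
  assignments <- assignments[rownames(v)]
  names(assignments) <- rownames(v)
  assignments[is.na(assignments)] <- 0L
  # compact ids to 1..k by descending size
  ids <- sort(unique(assignments[assignments > 0L]))
  sz <- vapply(ids, function(m) sum(assignments == m), 0L)
  remap <- setNames(integer(length(ids)), ids)
  remap[as.character(ids[order(-sz)])] <- seq_along(ids)
  out <- assignments
  out[assignments > 0L] <- remap[as.character(assignments[assignments > 0L])]
  finalizeModuleSet(v, out, parameters)
}

#' Rank putative driver genes of a module
#'
#' Driver genes are members with the highest intramodular connectivity,
#' i.e. the largest kME to their own module eigengene; ties break
#' lexicographically.
#'
#' @param ms a \linkS4class{ModuleSet}.
#' @param module module id or label.
#' @param n number of genes to return.
#' @return character vector of gene ids, strongest first.
#' @export
driverGenes <- function(ms, module, n = 10L) {
  m <- moduleId(ms, module)
  genes <- moduleGenes(ms, m)
  if (length(genes) < n)
    stop("module has only ", length(genes), " members; n = ", n)
  k <- ms@kme[genes, m]
  genes[order(-k, genes)][seq_len(n)]
}

#' Export a hub subnetwork as node and edge tables
#'
#' Selects the \code{topN} members of a module by kME and emits
#' Cytoscape-compatible node (gene, kME, q) and edge (gene_i, gene_j,
#' topological overlap weight) tables.
#'
#' @param ms a \linkS4class{ModuleSet}.
#' @param tom topological overlap matrix covering the module members.
#' @param module module id or label.
#' @param topN number of hub genes to keep (default 100).
#' @param nodeFile,edgeFile optional TSV output paths.
#' @return list with data.frames \code{nodes} and \code{edges}.
#' @export
exportSubnetwork <- function(ms, tom, module, topN = 100L,
                             nodeFile = NULL, edgeFile = NULL) {
  m <- moduleId(ms, module)
  genes <- moduleGenes(ms, m)
  if (length(genes) < topN) {
    warning("module smaller than topN; exporting all ", length(genes),
            " members")
    topN <- length(genes)
  }
  k <- ms@kme[genes, m]
  sel <- genes[order(-k, genes)][seq_len(topN)]
  nodes <- data.frame(gene = sel, kme = ms@kme[sel, m],
                      q = ms@kmeQ[sel, m], row.names = NULL)
  pairs <- which(upper.tri(matrix(0, topN, topN)), arr.ind = TRUE)
  edges <- data.frame(gene_i = sel[pairs[, 1L]], gene_j = sel[pairs[, 2L]],
                      weight = tom[cbind(sel[pairs[, 1L]],
                                         sel[pairs[, 2L]])])
  if (!is.null(nodeFile))
    write.table(nodes, nodeFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(edgeFile))
    write.table(edges, edgeFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(nodes = nodes, edges = edges)
}
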