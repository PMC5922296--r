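#' @include AllClasses.R dataio.R
NULL

#' Hypergeometric gene set overlap test
#'
#' Upper-tail hypergeometric p for the overlap of two gene sets within a
#' universe: \eqn{k = |A \cap B|}, \eqn{p = P[X \ge k]} with X
#' hypergeometric(N = |universe|, K = |A|, n = |B|). Genes outside the
#' universe are dropped with a message; the test is symmetric in A and B.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe character vector defining the background.
#' @return one-row data.frame (k, sizeA, sizeB, universeSize, expected, p).
#' @export
hypergeomOverlap <- function(setA, setB, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  a <- unique(setA); b <- unique(setB)
  dropA <- sum(!a %in% universe); dropB <- sum(!b %in% universe)
  if (dropA + dropB > 0)
    message("dropped ", dropA, " / ", dropB,
            " genes of setA / setB outside the universe")
  a <- intersect(a, universe); b <- intersect(b, universe)
  k <- length(intersect(a, b))
  N <- length(universe)
  p <- phyper(k - 1, length(a), N - length(a), length(b),
              lower.tail = FALSE)
  data.frame(k = k, sizeA = length(a), sizeB = length(b),
             universeSize = N, expected = length(a) * length(b) / N,
             p = p)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score.
# scores must already be sorted (descending); hit is a logical mask.
runningES <- function(scores, hit, weight = 1) {
  N <- length(scores)
  Nh <- sum(hit)
  if (Nh == 0L) stop("gene set disjoint from ranked list")
  if (Nh == N) return(1)    # degenerate all-hit walk; documented convention
  inc <- numeric(N)
  w <- abs(scores[hit])^weight
  if (sum(w) == 0) w <- rep(1, Nh)   # all-zero scores: unweighted steps
  inc[hit] <- w / sum(w)
  inc[!hit] <- -1 / (N - Nh)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# Order a named score vector descending, ties broken by gene id so results
# are platform-independent.
orderRanked <- function(scores) {
  if (is.null(names(scores))) stop("ranked scores must be named by gene")
  if (anyDuplicated(names(scores))) stop("ranked list has duplicate genes")
  if (any(!is.finite(scores))) stop("ranked scores must be finite")
  scores[order(-scores, names(scores))]
}

#' Preranked GSEA
#'
#' Weighted Kolmogorov-Smirnov enrichment of gene sets in a ranked list:
#' hit steps are proportional to \eqn{|score|^{weight}} (normalized), miss
#' steps uniform, and the enrichment score ES is the extreme deviation of
#' the running sum. The null permutes gene labels (random sets of equal
#' size); NES = ES / mean(|null ES| of the same sign), the nominal p is the
#' same-sign exceedance with add-one correction, and FDR q uses the
#' sign-stratified pooled-null GSEA convention (\code{fdr = "BH"} for
#' plain BH across sets).
#'
#' @param scores named numeric vector ranking the genes (sorted internally,
#'   descending, ties broken by gene id).
#' @param geneSets a \linkS4class{GeneSetList}, list of character vectors,
#'   or a single character vector.
#' @param weight score weighting exponent (default 1; 0 = classic KS).
#' @param nPerm gene-label permutations (default 1000).
#' @param seed RNG seed.
#' @param fdr "gsea" (default) or "BH".
#' @return data.frame, one row per set (set, size, ES, NES, p, q).
#' @export
gseaPreranked <- function(scores, geneSets, weight = 1, nPerm = 1000L,
                          seed = NULL, fdr = c("gsea", "BH")) {
  fdr <- match.arg(fdr)
  scores <- orderRanked(scores)
  genes <- names(scores)
  sets <- if (is(geneSets, "GeneSetList")) geneSets@sets
          else if (is.list(geneSets)) geneSets
          else list(set = geneSets)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  N <- length(genes)
  out <- data.frame(set = names(sets), size = NA_integer_, ES = NA_real_,
                    NES = NA_real_, p = NA_real_, q = NA_real_)
  nullNES <- list()
  withSeed(seed, {
    for (i in seq_along(sets)) {
      hit <- genes %in% sets[[i]]
      Nh <- sum(hit)
      if (Nh == 0L) stop("gene set '", names(sets)[i],
                         "' disjoint from ranked list")
      es <- runningES(scores, hit, weight)
      nulls <- vapply(seq_len(nPerm), function(j) {
        h <- logical(N); h[sample.int(N, Nh)] <- TRUE
        runningES(scores, h, weight)
      }, 0)
      mPos <- mean(nulls[nulls >= 0]); mNeg <- mean(abs(nulls[nulls < 0]))
      nes <- if (es >= 0) es / mPos else -abs(es) / mNeg
      sameSign <- if (es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
      p <- (1 + sum(abs(sameSign) >= abs(es))) / (1 + length(sameSign))
      out$size[i] <- Nh; out$ES[i] <- es; out$NES[i] <- nes; out$p[i] <- p
      nullNES[[i]] <- ifelse(nulls >= 0, nulls / mPos, nulls / mNeg)
    }
  })
  if (fdr == "BH" || length(sets) == 1L) {
    out$q <- p.adjust(out$p, "BH")
  } else {
    pool <- unlist(nullNES, use.names = FALSE)
    out$q <- vapply(seq_len(nrow(out)), function(i) {
      nes <- out$NES[i]
      if (nes >= 0) {
        top <- mean(pool[pool >= 0] >= nes)
        bot <- mean(out$NES[out$NES >= 0] >= nes)
      } else {
        top <- mean(pool[pool < 0] <= nes)
        bot <- mean(out$NES[out$NES < 0] <= nes)
      }
      min(1, max(0, top / max(bot, .Machine$double.eps)))
    }, 0)
  }
  out
}

#' Single-sample GSEA
#'
#' Per-sample gene-set scores from absolute expression: within each sample
#' genes are ranked descending (ties broken by gene id) and the score is the
#' sum over all ranks of the difference between the weighted hit ECDF
#' (weight \eqn{(N - i + 1)^\alpha} at position i, i.e. descending rank
#' value to the alpha) and the uniform miss ECDF. With
#' \code{normalize = TRUE} the whole matrix is divided by its score range.
#' Scores are rank-based and therefore invariant to adding a constant to a
#' sample.
#'
#' @param expr an \linkS4class{ExpressionDataset} or gene x sample matrix.
#' @param geneSets \linkS4class{GeneSetList} or named list.
#' @param alpha rank weighting exponent (default 0.25).
#' @param normalize divide by the global score range (default TRUE).
#' @return sample x set score matrix.
#' @export
ssgsea <- function(expr, geneSets, alpha = 0.25, normalize = TRUE) {
  v <- if (is(expr, "ExpressionDataset")) exprValues(expr) else as.matrix(expr)
  sets <- if (is(geneSets, "GeneSetList")) geneSets@sets else geneSets
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  N <- nrow(v)
  for (nm in names(sets))
    if (!length(intersect(sets[[nm]], rownames(v))))
      stop("gene set '", nm, "' shares no genes with the data")
  out <- matrix(NA_real_, ncol(v), length(sets),
                dimnames = list(colnames(v), names(sets)))
  for (s in seq_len(ncol(v))) {
    ord <- order(-v[, s], rownames(v))
    genesOrd <- rownames(v)[ord]
    wRank <- (N - seq_len(N) + 1)^alpha
    for (j in seq_along(sets)) {
      hit <- genesOrd %in% sets[[j]]
      Nh <- sum(hit)
      wh <- wRank * hit
      cumHit <- cumsum(wh) / sum(wh)
      cumMiss <- cumsum(!hit) / (N - Nh)
      out[s, j] <- sum(cumHit - cumMiss)
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  out
}

#' Module gene sets of a ModuleSet
#'
#' @param ms a \linkS4class{ModuleSet}.
#' @return A \linkS4class{GeneSetList}, one set per module (M1..Mk).
#' @export
moduleGeneSets <- function(ms) {
  stopifnot(is(ms, "ModuleSet"))
  ids <- seq_len(nModules(ms))
  sets <- lapply(ids, function(m) moduleGenes(ms, m))
  names(sets) <- rownames(ms@eigengenes)
  GeneSetList(sets, rep("coexpression module", length(sets)))
}

#' Cross-species module conservation via preranked GSEA
#'
#' Maps module gene sets through an orthology/symbol table
#' (\code{\link{mapGeneSymbols}}) and tests each for enrichment in a ranked
#' list from the other species (e.g. human blood-vs-epidermis differential
#' statistic). Modules mapping to fewer than \code{minMapped} genes in the
#' list are skipped with a warning.
#'
#' @param moduleSets \linkS4class{GeneSetList} (e.g. from
#'   \code{\link{moduleGeneSets}}).
#' @param rankedList named numeric ranking vector in target-species ids.
#' @param mappingTable two-column from/to data.frame, or NULL for the
#'   upper-case fallback.
#' @param nPerm,seed,weight passed to \code{\link{gseaPreranked}}.
#' @param minMapped minimum mapped genes per module (default 5).
#' @return data.frame as from \code{\link{gseaPreranked}}.
#' @export
moduleConservationTest <- function(moduleSets, rankedList,
                                   mappingTable = NULL, nPerm = 1000L,
                                   seed = NULL, weight = 1,
                                   minMapped = 5L) {
  stopifnot(is(moduleSets, "GeneSetList"))
  mapFun <- if (is.null(mappingTable)) {
    toupper
  } else {
    from <- as.character(mappingTable[[1L]])
    to <- as.character(mappingTable[[2L]])
    function(g) unname(setNames(to, from)[g])
  }
  listGenes <- names(orderRanked(rankedList))
  mappedSets <- list()
  for (nm in names(moduleSets@sets)) {
    m <- mapFun(moduleSets@sets[[nm]])
    m <- intersect(unique(m[!is.na(m)]), listGenes)
    if (length(m) < minMapped) {
      warning("module '", nm, "' maps to ", length(m), " gene(s) (< ",
              minMapped, ") in the ranked list; skipped")
    } else mappedSets[[nm]] <- m
  }
  if (!length(mappedSets))
    return(data.frame(set = character(), size = integer(),
                      ES = numeric(), NES = numeric(),
                      p = numeric(), q = numeric()))
  gseaPreranked(rankedList, mappedSets, weight = weight,
                nPerm = nPerm, seed = seed)
}
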