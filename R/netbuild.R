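#' @include AllClasses.R utils.R
NULL

#' Gene-gene Pearson correlation matrix
#'
#' Pairwise Pearson correlation of gene expression profiles on the log2
#' scale, the basis of the weighted coexpression network.
#'
#' @param expr an \linkS4class{ExpressionDataset} (or plain gene x sample
#'   matrix) with at least 3 samples and no zero-variance gene.
#' @return symmetric gene x gene matrix with unit diagonal.
#' @export
correlationMatrix <- function(expr) {
  v <- if (is(expr, "ExpressionDataset")) exprValues(expr) else as.matrix(expr)
  if (ncol(v) < 3L) stop("need at least 3 samples")
  s <- sqrt(rowVars2(v))
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(v)[s == 0], 5L), collapse = ", "),
         " - filter before network construction")
  r <- cor(t(v))
  diag(r) <- 1
  r
}

#' Soft-thresholded adjacency
#'
#' Raises correlations to the soft power beta. In \code{"unsigned"} mode
#' \eqn{a = |r|^\beta}; in \code{"signed_hybrid"} mode negative correlations
#' are clipped to 0 (\eqn{a = r^\beta} for r > 0), which prevents
#' anti-correlated programs from fusing into one module. The diagonal is set
#' to 0 for connectivity computations.
#'
#' @param corr correlation matrix from \code{\link{correlationMatrix}}.
#' @param power soft-threshold exponent beta (>= 1).
#' @param mode "signed_hybrid" (default) or "unsigned".
#' @return symmetric adjacency matrix with entries in [0, 1], zero diagonal.
#' @export
adjacencyMatrix <- function(corr, power,
                            mode = c("signed_hybrid", "unsigned")) {
  mode <- match.arg(mode)
  if (power < 1) stop("power must be >= 1")
  a <- if (mode == "unsigned") abs(corr) else pmax(corr, 0)
  a <- a^power
  diag(a) <- 0
  a
}

#' Scan candidate soft powers for approximate scale-free topology
#'
#' For each candidate power the connectivity distribution is binned and the
#' R-squared of the log10(freq) ~ log10(k) regression recorded; the chosen
#' power is the smallest candidate reaching \code{r2Threshold}, with a
#' fallback to 6 (and a warning) when no candidate qualifies, as is common
#' on weakly modular data.
#'
#' @param expr an \linkS4class{ExpressionDataset} or matrix.
#' @param candidates integer vector of powers to scan.
#' @param r2Threshold scale-free fit threshold (default 0.8).
#' @param mode network mode, see \code{\link{adjacencyMatrix}}.
#' @param nBreaks connectivity histogram bins for the fit.
#' @param minMeanK candidates whose mean connectivity falls below this are
#'   excluded from qualification (default 0.01): a near-empty network's
#'   connectivity distribution fits a power law spuriously well, which
#'   would otherwise make very high powers "qualify" even on pure noise.
#' @return A \linkS4class{SoftPowerScan}.
#' @export
pickSoftPower <- function(expr, candidates = 1:20, r2Threshold = 0.8,
                          mode = c("signed_hybrid", "unsigned"),
                          nBreaks = 10L, minMeanK = 0.01) {
  mode <- match.arg(mode)
  corr <- correlationMatrix(expr)
  if (nrow(corr) < 50L)
    warning("fewer than 50 genes: scale-free fit is unreliable")
  scan <- data.frame(power = as.integer(candidates), r2 = NA_real_,
                     slope = NA_real_, meanK = NA_real_)
  for (i in seq_along(candidates)) {
    a <- adjacencyMatrix(corr, candidates[i], mode)
    k <- rowSums(a)
    scan$meanK[i] <- mean(k)
    scan[i, c("r2", "slope")] <- scaleFreeFit(k, nBreaks)
  }
  ok <- which(!is.na(scan$r2) & scan$r2 >= r2Threshold &
                scan$meanK >= minMeanK & scan$slope < 0)
  if (length(ok)) {
    chosen <- scan$power[ok[1L]]
  } else {
    chosen <- 6L
    warning("no candidate power reached R^2 >= ", r2Threshold,
            "; falling back to power 6")
  }
  new("SoftPowerScan", scan = scan, chosenPower = as.integer(chosen),
      r2Threshold = r2Threshold)
}

# R^2 and slope of log10 p(k) vs log10 k over nBreaks connectivity bins.
scaleFreeFit <- function(k, nBreaks = 10L) {
  k <- k[k > 0]
  if (length(k) < nBreaks) return(c(NA_real_, NA_real_))
  cut1 <- cut(k, breaks = nBreaks)
  freq <- tapply(k, cut1, length)
  kmean <- tapply(k, cut1, mean)
  keep <- !is.na(freq) & freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(keep) < 3L) return(c(NA_real_, NA_real_))
  x <- log10(kmean[keep]); y <- log10(freq[keep] / sum(freq[keep]))
  fit <- stats::lm(y ~ x)
  c(summary(fit)$r.squared, stats::coef(fit)[2L])
}

#' Topological overlap matrix
#'
#' Smooths the adjacency by shared-neighbor structure:
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'                       {\min(k_i, k_j) + 1 - a_{ij}}}
#' for i != j, with \eqn{TOM_{ii} = 1} and \eqn{k_i = \sum_u a_{iu}}.
#' 1 - TOM is the dissimilarity clustered by \code{\link{detectModules}},
#' and TOM entries are the edge weights of exported hub subnetworks.
#'
#' @param adj adjacency matrix with zero diagonal
#'   (see \code{\link{adjacencyMatrix}}).
#' @return symmetric matrix with entries in [0, 1], unit diagonal.
#' @export
topologicalOverlap <- function(adj) {
  k <- rowSums(adj)
  num <- adj %*% adj + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  tom <- (tom + t(tom)) / 2   # enforce exact symmetry against FP noise
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}
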