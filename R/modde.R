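#' @include AllClasses.R modules.R
NULL

# Vectorized Welch two-sample t over the rows of X.
# WA, WB: n x P 0/1 indicator matrices of arm membership per permutation
# (columns); returns list of G x P matrices.
welchRows <- function(X, WA, WB) {
  nA <- sum(WA[, 1L]); nB <- sum(WB[, 1L])
  X2 <- X * X
  MA <- (X %*% WA) / nA; MB <- (X %*% WB) / nB
  VA <- ((X2 %*% WA) - nA * MA * MA) / (nA - 1)
  VB <- ((X2 %*% WB) - nB * MB * MB) / (nB - 1)
  VA[VA < 0] <- 0; VB[VB < 0] <- 0
  sa <- VA / nA; sb <- VB / nB
  se <- sqrt(sa + sb)
  t <- (MB - MA) / se
  t[se == 0] <- 0
  df <- (sa + sb)^2 / (sa^2 / (nA - 1) + sb^2 / (nB - 1))
  df[!is.finite(df)] <- nA + nB - 2
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  z <- qnorm(p / 2, lower.tail = FALSE) * sign(t)
  list(effect = MB - MA, t = t, df = df, p = p, z = z)
}

# Align a trait design to the columns of an expression matrix.
alignDesign <- function(design, v) {
  if ("sample_id" %in% names(design) && !is.null(colnames(v))) {
    idx <- match(colnames(v), design$sample_id)
    if (anyNA(idx)) stop("design lacks sample(s): ",
                         paste(colnames(v)[is.na(idx)], collapse = ", "))
    design <- design[idx, , drop = FALSE]
  }
  if (nrow(design) != ncol(v))
    stop("design rows must match expression samples")
  design
}

resolveContrast <- function(design, contrast) {
  if (length(contrast) != 3L)
    stop("contrast must be c(variable, groupB, groupA)")
  variable <- contrast[[1L]]
  if (!variable %in% names(design)) stop("unknown design column: ", variable)
  lev <- design[[variable]]
  idxB <- which(lev == contrast[[2L]]); idxA <- which(lev == contrast[[3L]])
  if (length(idxA) < 2L || length(idxB) < 2L)
    stop("each contrast arm needs at least 2 samples")
  list(variable = variable, idxA = idxA, idxB = idxB)
}

#' Per-gene differential expression (Welch t)
#'
#' Welch two-sample t test of each gene on the log2 scale between two arms
#' of a design contrast, reporting the effect (mean group B - group A),
#' the t statistic, two-sided p and the signed z score
#' \eqn{z = \Phi^{-1}(1 - p/2)\,\mathrm{sign}(effect)} consumed by
#' \code{\link{modDE}}.
#'
#' @param expr an \linkS4class{ExpressionDataset} or gene x sample matrix.
#' @param design trait design data.frame aligned with the samples.
#' @param contrast character vector \code{c(variable, groupB, groupA)},
#'   e.g. \code{c("condition", "allo_dep", "allo")}.
#' @return data.frame (gene, effect, t, df, p, z).
#' @export
geneDE <- function(expr, design, contrast) {
  v <- if (is(expr, "ExpressionDataset")) exprValues(expr) else as.matrix(expr)
  design <- alignDesign(design, v)
  ct <- resolveContrast(design, contrast)
  n <- ncol(v)
  WA <- matrix(0, n, 1L); WA[ct$idxA, 1L] <- 1
  WB <- matrix(0, n, 1L); WB[ct$idxB, 1L] <- 1
  w <- welchRows(v, WA, WB)
  data.frame(gene = rownames(v), effect = drop(w$effect), t = drop(w$t),
             df = drop(w$df), p = drop(w$p), z = drop(w$z),
             row.names = NULL)
}

# Stratified label permutations for a two-arm contrast. Returns an
# n x P 0/1 matrix marking arm-A membership; column 0 sizes are preserved
# within every stratum. Also reports the number of distinct relabelings.
strataPermutations <- function(strata, idxA, idxB, nPerm) {
  sel <- c(idxA, idxB)
  armA <- sel %in% idxA
  st <- strata[sel]
  distinct <- prod(vapply(split(armA, st), function(a)
    choose(length(a), sum(a)), 0))
  WA <- matrix(0, length(strata), nPerm)
  for (p in seq_len(nPerm)) {
    take <- unlist(lapply(split(seq_along(sel), st), function(i) {
      i[sample.int(length(i), sum(armA[i]))]
    }), use.names = FALSE)
    WA[sel[take], p] <- 1
  }
  list(WA = WA, distinct = distinct)
}

#' Module-level differential expression (modDE)
#'
#' Tests each module for differential expression between two arms of a
#' contrast, combining per-gene evidence with direction-of-effect
#' consistency against the module's correlation structure. For module m with
#' member genes g, orientation \eqn{s_g = \mathrm{sign}(kME_{g,m})} and
#' weight \eqn{w_g = |kME_{g,m}|} give the consistency statistic
#' \deqn{T_m = \sum_g w_g s_g z_g / \sqrt{\sum_g w_g^2},}
#' a kME-signed, kME-weighted Stouffer combination of the per-gene signed z
#' scores. Its null is a sample-label permutation (stratified by tissue when
#' several tissues are present, so condition effects are not confounded with
#' tissue), which respects the inter-gene correlation an analytic Stouffer
#' null would ignore; the two-sided empirical p carries the add-one
#' correction. The excess component counts member genes with p below
#' \code{alpha0} against the hypergeometric expectation over all genes.
#' The headline module p is the consistency component; BH q is computed
#' across modules for each component separately.
#'
#' @param ms \linkS4class{ModuleSet} with kME (from
#'   \code{\link{detectModules}} or
#'   \code{\link{moduleSetFromAssignments}}).
#' @param expr an \linkS4class{ExpressionDataset} or matrix.
#' @param design trait design data.frame aligned with the samples.
#' @param contrast \code{c(variable, groupB, groupA)}.
#' @param nPerm number of label permutations (default 10000).
#' @param seed RNG seed (fixed seed = bitwise reproducible p).
#' @param alpha0 per-gene significance level of the excess component.
#' @param strata stratification: NULL (default) stratifies by tissue when
#'   the design has several tissues; FALSE disables; or a design column
#'   name.
#' @return A \linkS4class{ModDEResult}.
#' @export
modDE <- function(ms, expr, design, contrast, nPerm = 10000L, seed = NULL,
                  alpha0 = 0.05, strata = NULL) {
  v <- if (is(expr, "ExpressionDataset")) exprValues(expr) else as.matrix(expr)
  design <- alignDesign(design, v)
  ct <- resolveContrast(design, contrast)
  stVec <- if (isFALSE(strata)) {
    rep("all", nrow(design))
  } else if (is.null(strata)) {
    if ("tissue" %in% names(design) &&
        length(unique(design$tissue)) > 1L) design$tissue
    else rep("all", nrow(design))
  } else design[[strata]]

  obs <- geneDE(v, design, contrast)
  assign <- moduleAssignments(ms)
  ids <- sort(unique(assign[assign > 0L]))
  present <- list()
  for (m in ids) {
    genes <- intersect(names(assign)[assign == m], rownames(v))
    if (!length(genes)) {
      warning("module M", m, " absent from expression data; skipped")
      next
    }
    present[[paste0("M", m)]] <- genes
  }
  if (!length(present)) stop("no module overlaps the expression data")

  memberGenes <- unique(unlist(present, use.names = FALSE))
  S <- matrix(0, length(present), length(memberGenes),
              dimnames = list(names(present), memberGenes))
  for (i in seq_along(present)) {
    g <- present[[i]]
    m <- moduleId(ms, names(present)[i])
    w <- ms@kme[g, m]
    S[i, g] <- w / sqrt(sum(w^2))        # w_g * s_g, normalized
  }
  zObs <- setNames(obs$z, obs$gene)[memberGenes]
  Tobs <- drop(S %*% zObs)

  Tnull <- matrix(NA_real_, length(present), nPerm)
  X <- v[memberGenes, , drop = FALSE]
  withSeed(seed, {
    perms <- strataPermutations(stVec, ct$idxA, ct$idxB, nPerm)
    if (perms$distinct < 20)
      stop("fewer than 20 distinct label permutations; ",
           "insufficient samples for modDE")
    sel <- c(ct$idxA, ct$idxB)
    chunk <- 2000L
    for (start in seq(1L, nPerm, by = chunk)) {
      cols <- start:min(start + chunk - 1L, nPerm)
      WA <- perms$WA[, cols, drop = FALSE]
      WB <- matrix(0, nrow(WA), length(cols))
      WB[sel, ] <- 1
      WB <- WB - WA
      Tnull[, cols] <- S %*% welchRows(X, WA, WB)$z
    }
  })
  consistencyP <- vapply(seq_along(present), function(i)
    (1 + sum(abs(Tnull[i, ]) >= abs(Tobs[i]))) / (nPerm + 1), 0)

  N <- nrow(v)
  K <- sum(obs$p < alpha0)
  excessK <- vapply(present, function(g)
    sum(obs$p[match(g, obs$gene)] < alpha0), 0L)
  sizes <- lengths(present)
  excessP <- phyper(excessK - 1L, K, N - K, sizes, lower.tail = FALSE)
  tb <- data.frame(module = names(present), size = as.integer(sizes),
                   T = Tobs, consistencyP = consistencyP,
                   consistencyQ = p.adjust(consistencyP, "BH"),
                   excessK = as.integer(excessK),
                   excessExpected = sizes * K / N,
                   excessP = excessP,
                   excessQ = p.adjust(excessP, "BH"),
                   row.names = NULL)
  new("ModDEResult", table = tb, geneTable = obs,
      nPerm = as.integer(nPerm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nullMethod = if (length(unique(stVec)) > 1L)
        "stratified_label_permutation" else "label_permutation")
}

#' Join module-trait and modDE significance for the site-vs-perturbation map
#'
#' Produces the table behind the scatter of trait correlation significance
#' (x) against module differential-expression significance (y), flagging
#' the module that maximizes both coordinates among those passing
#' (trait p < 0.01, modDE q < 0.05) — the candidate site-specific,
#' perturbation-responsive program.
#'
#' @param modde a \linkS4class{ModDEResult}.
#' @param mtm a \linkS4class{ModuleTraitMatrix}.
#' @param trait trait column name (e.g. \code{"tissue_epidermis"}).
#' @return data.frame (module, traitNegLogP, moddeNegLogP, flagged).
#' @export
moddeTraitTable <- function(modde, mtm, trait) {
  stopifnot(is(modde, "ModDEResult"), is(mtm, "ModuleTraitMatrix"))
  if (!trait %in% colnames(mtm@p)) stop("unknown trait: ", trait)
  common <- intersect(modde@table$module, rownames(mtm@p))
  if (!length(common)) stop("module sets are disjoint")
  tb <- modde@table[match(common, modde@table$module), ]
  out <- data.frame(module = common,
                    traitNegLogP = -log10(mtm@p[common, trait]),
                    moddeNegLogP = -log10(tb$consistencyP),
                    flagged = FALSE, row.names = NULL)
  pass <- mtm@p[common, trait] < 0.01 & tb$consistencyQ < 0.05
  if (any(pass)) {
    score <- out$traitNegLogP + out$moddeNegLogP
    score[!pass] <- -Inf
    out$flagged[which.max(score)] <- TRUE
  }
  out
}
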