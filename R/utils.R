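#' @include AllClasses.R
NULL

# Run `expr` under a fixed RNG seed when one is given, without disturbing
# the caller's RNG state; with seed = NULL the current stream is used.
withSeed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

# Row variances of a numeric matrix (no matrixStats dependency).
rowVars2 <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  (rowSums(x * x) - n * m * m) / (n - 1)
}

# Scale rows to mean 0, sd 1. Errors on zero-variance rows unless allow0.
scaleRows <- function(x, allow0 = FALSE) {
  m <- rowMeans(x)
  s <- sqrt(rowVars2(x))
  if (!allow0 && any(s == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(x)[s == 0], 5L), collapse = ", "))
  s[s == 0] <- 1
  (x - m) / s
}

# Two-sided p for a Pearson correlation via the t transform.
corPvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r * r, .Machine$double.eps))
  p <- 2 * pt(t, df = n - 2, lower.tail = FALSE)
  pmin(1, pmax(p, .Machine$double.xmin))
}

# Pearson correlation of the columns of x with the columns of y, both
# matrices over the same rows (observations).
corXY <- function(x, y) stats::cor(x, y)

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same genes,
#' used to compare detected modules with planted truth. 1 = identical
#' partitions (up to label renaming), 0 = chance agreement.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return the adjusted Rand index, a number <= 1.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
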