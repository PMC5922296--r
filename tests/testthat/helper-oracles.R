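# Independent reference implementations used to cross-check the package.
# These deliberately use naive algorithms (triple loops, exhaustive
# enumeration, numerical integration) so they share no code path with the
# implementation under test.

# Topological overlap by explicit triple loop.
tomOracle <- function(adj) {
  n <- nrow(adj)
  out <- matrix(1, n, n, dimnames = dimnames(adj))
  k <- rowSums(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) s <- s + adj[i, u] * adj[u, j]
    out[i, j] <- (s + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  out
}

# Upper-tail overlap probability by exhaustive enumeration of all draws of
# size b from universe 1..N, with set A = 1..a.
hyperOracle <- function(N, a, b, k) {
  draws <- utils::combn(N, b)
  overlap <- colSums(matrix(draws <= a, nrow = b))
  mean(overlap >= k)
}

# Student-t upper tail by numerical integration of the density (no pt()).
tUpperOracle <- function(t, df) {
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  stats::integrate(dens, t, Inf, rel.tol = 1e-12)$value
}

# Weighted KS running-sum enrichment score, re-derived step by step.
esOracle <- function(scores, hit, weight = 1) {
  N <- length(scores)
  Nh <- sum(hit)
  if (Nh == N) return(1)
  denomHit <- sum(abs(scores[hit])^weight)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- if (hit[i]) run + abs(scores[i])^weight / denomHit
           else run - 1 / (N - Nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# ssGSEA score of one gene set in one sample, per-rank summation.
ssgseaOracle <- function(x, set, alpha = 0.25) {
  ord <- order(-x, names(x))
  genes <- names(x)[ord]
  N <- length(genes)
  hit <- genes %in% set
  wsum <- sum(((N - seq_len(N) + 1)^alpha)[hit])
  cumHit <- 0; cumMiss <- 0; es <- 0
  for (i in seq_len(N)) {
    if (hit[i]) cumHit <- cumHit + (N - i + 1)^alpha / wsum
    else cumMiss <- cumMiss + 1 / (N - sum(hit))
    es <- es + (cumHit - cumMiss)
  }
  es
}

# Welch two-sample t by direct formula on two vectors.
welchOracle <- function(xa, xb) {
  va <- var(xa); vb <- var(xb)
  se2 <- va / length(xa) + vb / length(xb)
  t <- (mean(xb) - mean(xa)) / sqrt(se2)
  df <- se2^2 / ((va / length(xa))^2 / (length(xa) - 1) +
                 (vb / length(xb))^2 / (length(xb) - 1))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}
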