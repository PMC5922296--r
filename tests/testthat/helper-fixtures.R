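# Small fixture builders shared across test files.

# Plain expression matrix with deterministic dimnames.
makeExpr <- function(values, nGenes = nrow(values), nSamples = ncol(values)) {
  m <- matrix(values, nGenes, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  m
}

# A tiny planted-module dataset: k modules of `size` genes driven by
# independent latent factors (loading lambda), plus background noise genes.
tinyPlanted <- function(k = 2, size = 20, nBackground = 40, nSamples = 30,
                        lambda = 0.9, sigma = 0.5, seed = 1) {
  withr::with_seed(seed, {
    f <- matrix(rnorm(k * nSamples), k, nSamples)
    mem <- rep(c(seq_len(k), 0L), c(rep(size, k), nBackground))
    n <- length(mem)
    x <- matrix(rnorm(n * nSamples, sd = sigma), n, nSamples)
    for (m in seq_len(k))
      x[mem == m, ] <- x[mem == m, ] + lambda * matrix(
        f[m, ], sum(mem == m), nSamples, byrow = TRUE)
    dimnames(x) <- list(sprintf("g%03d", seq_len(n)),
                        sprintf("s%02d", seq_len(nSamples)))
    list(x = x, membership = stats::setNames(mem, rownames(x)), factors = f)
  })
}

# Minimal trait design for a given sample id vector.
tinyDesign <- function(sampleIds, tissues, conditions) {
  data.frame(sample_id = sampleIds, tissue = tissues,
             condition = conditions,
             replicate = seq_along(sampleIds),
             stringsAsFactors = FALSE)
}
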