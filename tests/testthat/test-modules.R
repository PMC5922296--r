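test_that("eigengenes summarize their members with the right orientation", {
  # module of exact copies of one profile: |r| with each member is 1
  base <- c(1, 3, 2, 5, 4, 6)
  v <- rbind(g1 = base, g2 = base, g3 = base)
  colnames(v) <- paste0("s", 1:6)
  me <- moduleEigengenes(v, setNames(c(1L, 1L, 1L), rownames(v)))
  expect_equal(abs(cor(me["M1", ], base)), 1, tolerance = 1e-10)
  expect_equal(mean(me["M1", ]), 0, tolerance = 1e-12)
  expect_equal(var(me["M1", ]), 1, tolerance = 1e-12)
  # mean member correlation is positive
  expect_gt(cor(me["M1", ], base), 0)

  # exactly balanced module (x and -x): tie broken by the first member
  v2 <- rbind(gA = base, gB = -base)
  colnames(v2) <- paste0("s", 1:6)
  me2 <- moduleEigengenes(v2, setNames(c(1L, 1L), rownames(v2)))
  expect_gte(cor(me2["M1", ], v2["gA", ]), 0)

  # single-gene module: the standardized gene itself
  me3 <- moduleEigengenes(v2, setNames(c(1L, 0L), rownames(v2)))
  expect_equal(me3["M1", ], (base - mean(base)) / sd(base),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("eigengene tracks the planted latent factor", {
  planted <- tinyPlanted(k = 1, size = 40, nBackground = 0, nSamples = 50,
                         lambda = 0.8, sigma = sqrt(1 - 0.64), seed = 3)
  me <- moduleEigengenes(planted$x, planted$membership)
  expect_gte(abs(cor(me["M1", ], planted$factors[1, ])), 0.95)
})

test_that("kME statistics match the t-distribution oracle", {
  withr::local_seed(11)
  v <- makeExpr(rnorm(5 * 5), 5, 5)
  me <- moduleEigengenes(v, setNames(c(1L, 1L, 1L, 0L, 0L), rownames(v)))
  kk <- kme(v, me)
  for (g in rownames(v)) {
    r <- cor(v[g, ], me["M1", ])
    expect_equal(kk$r[g, "M1"], r, tolerance = 1e-12)
    t <- abs(r) * sqrt(3 / (1 - r^2))
    expect_equal(kk$p[g, "M1"], 2 * tUpperOracle(t, 3), tolerance = 1e-10)
  }
  # gene identical to the eigengene
  v2 <- rbind(v, me1copy = me["M1", ] * 2 + 5)
  kk2 <- kme(v2, me)
  expect_equal(kk2$r["me1copy", "M1"], 1, tolerance = 1e-12)
  expect_lt(kk2$p["me1copy", "M1"], 1e-12)
  # orthogonal profile over 4 samples: r = 0, p = 1
  v3 <- rbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  colnames(v3) <- paste0("s", 1:4)
  me3 <- moduleEigengenes(v3, setNames(c(1L, 0L), rownames(v3)))
  kk3 <- kme(v3, me3)
  expect_equal(kk3$r["b", "M1"], 0, tolerance = 1e-12)
  expect_equal(kk3$p["b", "M1"], 1, tolerance = 1e-12)
  expect_error(kme(v3[, 1:2], me3[, 1:2, drop = FALSE]), "2 samples")
})

test_that("detectModules recovers planted modules and rejects noise", {
  sim <- generateSynthetic(standardScenarios(101)$recovery)
  ms <- detectModules(sim$expr, power = 6)
  ari <- adjustedRandIndex(moduleAssignments(ms), sim$truth@membership)
  expect_gte(ari, 0.9)
  expect_equal(nModules(ms), 6L)
  # module ids ordered by descending size
  expect_true(all(diff(moduleSizes(ms)) <= 0))
  # orientation invariant: mean member kME positive for every module
  for (m in seq_len(nModules(ms)))
    expect_gt(mean(ms@kme[moduleGenes(ms, m), m]), 0)

  noise <- withr::with_seed(9, makeExpr(rnorm(800 * 40), 800, 40))
  msN <- detectModules(noise, power = 6)
  expect_gte(mean(moduleAssignments(msN) == 0L), 0.95)
})

test_that("highly correlated planted modules are merged", {
  # two "modules" driven by one shared latent factor plus a little private
  # noise: eigengene correlation ~0.95, so they must merge at threshold .25
  withr::local_seed(21)
  n <- 40; f <- rnorm(n)
  x <- matrix(rnorm(80 * n, sd = 0.4), 80, n)
  x[1:40, ] <- x[1:40, ] + 0.9 * matrix(f, 40, n, byrow = TRUE)
  x[41:80, ] <- x[41:80, ] + 0.85 * matrix(f + rnorm(n, sd = 0.25),
                                           40, n, byrow = TRUE)
  dimnames(x) <- list(sprintf("g%03d", 1:80), sprintf("s%02d", 1:n))
  me1 <- eigengenes(moduleSetFromAssignments(
    x, setNames(rep(1:2, each = 40), rownames(x))))
  expect_gte(cor(me1[1, ], me1[2, ]), 0.9)
  ms <- detectModules(x, power = 6, minSize = 20)
  expect_equal(nModules(ms), 1L)
  expect_gte(sum(moduleAssignments(ms) > 0), 70)
})

test_that("module detection is deterministic and sample-order invariant", {
  planted <- tinyPlanted(k = 3, size = 40, nBackground = 200,
                         nSamples = 40, lambda = 0.85, sigma = 0.8,
                         seed = 13)
  ms1 <- detectModules(planted$x, power = 6)
  ms2 <- detectModules(planted$x, power = 6)
  expect_identical(moduleAssignments(ms1), moduleAssignments(ms2))
  perm <- withr::with_seed(4, sample(ncol(planted$x)))
  ms3 <- detectModules(planted$x[, perm], power = 6)
  expect_identical(moduleAssignments(ms1), moduleAssignments(ms3))
})

test_that("driver genes rank by kME with deterministic ties", {
  # module with graded loadings: strong drivers first
  withr::local_seed(7)
  n <- 60; lam <- seq(0.95, 0.3, length.out = 50)
  f <- rnorm(n)
  x <- lam %o% f + matrix(rnorm(50 * n, sd = 0.5), 50, n)
  x <- rbind(x, matrix(rnorm(10 * n), 10, n))
  dimnames(x) <- list(sprintf("g%03d", 1:60), sprintf("s%02d", 1:n))
  ms <- moduleSetFromAssignments(
    x, setNames(rep(c(1L, 0L), c(50, 10)), rownames(x)))
  top <- driverGenes(ms, 1, n = 10)
  expect_length(top, 10)
  # ranking correlates with the true (graded) loadings
  rk <- driverGenes(ms, 1, n = 50)
  trueStrength <- setNames(lam / sqrt(lam^2 + 0.25), rownames(x)[1:50])
  expect_gte(cor(match(names(trueStrength), rk), rank(-trueStrength),
                 method = "spearman"), 0.8)
  expect_error(driverGenes(ms, 1, n = 100), "only")
  expect_error(driverGenes(ms, 5), "unknown module")
})

test_that("subnetwork export is consistent with kME and TOM", {
  planted <- tinyPlanted(k = 1, size = 5, nBackground = 5, nSamples = 30,
                         lambda = 0.9, sigma = 0.4, seed = 2)
  ms <- moduleSetFromAssignments(planted$x, planted$membership)
  adj <- adjacencyMatrix(correlationMatrix(planted$x), 6)
  tom <- topologicalOverlap(adj)
  sub <- exportSubnetwork(ms, tom, 1, topN = 3)
  expect_equal(nrow(sub$nodes), 3L)
  expect_equal(nrow(sub$edges), 3L)          # C(3,2)
  expect_equal(sub$nodes$kme, unname(ms@kme[sub$nodes$gene, 1]))
  for (i in seq_len(nrow(sub$edges)))
    expect_equal(sub$edges$weight[i],
                 tom[sub$edges$gene_i[i], sub$edges$gene_j[i]])
  expect_warning(all5 <- exportSubnetwork(ms, tom, 1, topN = 10),
                 "smaller than topN")
  expect_equal(nrow(all5$nodes), 5L)
})
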