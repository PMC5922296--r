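moddeFixture <- function(scenario = "modde_coherent", seed = NULL) {
  scen <- standardScenarios(101)[[scenario]]
  if (!is.null(seed)) scen@seed <- as.integer(seed)
  sim <- generateSynthetic(scen)
  ms <- moduleSetFromAssignments(sim$expr, sim$truth@membership)
  list(sim = sim, ms = ms)
}

test_that("per-gene Welch test matches the hand computation", {
  xa <- c(1.2, 0.8, 1.5); xb <- c(2.5, 3.1, 2.2)
  v <- rbind(g1 = c(xa, xb), g2 = rep(1:2, 3))
  colnames(v) <- paste0("s", 1:6)
  d <- tinyDesign(colnames(v), rep("blood", 6),
                  rep(c("ctl", "trt"), each = 3))
  de <- geneDE(v, d, c("condition", "trt", "ctl"))
  oracle <- welchOracle(xa, xb)
  expect_equal(de$t[1], oracle$t, tolerance = 1e-10)
  expect_equal(de$df[1], oracle$df, tolerance = 1e-10)
  expect_equal(de$p[1], oracle$p, tolerance = 1e-10)
  expect_equal(de$effect[1], mean(xb) - mean(xa), tolerance = 1e-12)
  expect_equal(sign(de$z[1]), sign(de$effect[1]))
  expect_error(geneDE(v, d, c("condition", "trt", "nope")), "2 samples")
})

test_that("flat genes give null statistics and shifted genes respond", {
  withr::local_seed(51)
  d <- tinyDesign(paste0("s", 1:6), rep("blood", 6),
                  rep(c("a", "b"), each = 3))
  flat <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  colnames(flat) <- d$sample_id
  de <- geneDE(flat, d, c("condition", "b", "a"))
  expect_gt(de$p[1], 0.99)
  expect_equal(de$z[1], 0, tolerance = 1e-10)

  # 500 genes shifted by delta = 1 at sigma = 0.5, 3 vs 3
  x <- matrix(rnorm(500 * 6, sd = 0.5), 500, 6)
  x[, 4:6] <- x[, 4:6] + 1
  dimnames(x) <- list(sprintf("g%03d", 1:500), d$sample_id)
  de2 <- geneDE(x, d, c("condition", "b", "a"))
  # analytic Welch p at t = 1/(0.5*sqrt(2/3)) ~ 2.45, df ~ 4 is ~0.07:
  # shifted genes respond strongly relative to the null median of 0.5
  expect_lt(median(de2$p), 0.15)
  expect_gt(median(de2$z), 0)
})

test_that("modDE separates coherent from incoherent perturbations", {
  fx <- moddeFixture("modde_coherent")
  contrast <- c("condition", "allo_dep", "allo")
  res <- modDE(fx$ms, fx$sim$expr, fx$sim$design, contrast,
               nPerm = 2000, seed = 7)
  tb <- resultTable(res)
  target <- tb[tb$module == "M3", ]   # the perturbed, epidermis-linked one
  expect_lte(target$consistencyP, 0.005)
  expect_lt(target$excessP, 1e-20)
  expect_true(all(tb$consistencyP[tb$module != "M3"] > 0.05))

  fi <- moddeFixture("modde_incoherent")
  resI <- modDE(fi$ms, fi$sim$expr, fi$sim$design, contrast,
                nPerm = 2000, seed = 7)
  ti <- resultTable(resI)[resultTable(resI)$module == "M3", ]
  # same per-gene effect magnitude: the excess component still fires,
  # but direction is inconsistent with the correlation structure
  expect_lt(ti$excessP, 1e-20)
  expect_gt(ti$consistencyP, 0.05)
})

test_that("modDE invariants: sign flip, q >= p, reproducibility", {
  fx <- moddeFixture("modde_coherent")
  contrast <- c("condition", "allo_dep", "allo")
  res1 <- modDE(fx$ms, fx$sim$expr, fx$sim$design, contrast,
                nPerm = 300, seed = 13)
  res2 <- modDE(fx$ms, fx$sim$expr, fx$sim$design, contrast,
                nPerm = 300, seed = 13)
  expect_identical(resultTable(res1), resultTable(res2))
  tb <- resultTable(res1)
  expect_true(all(tb$consistencyQ >= tb$consistencyP - 1e-12))
  expect_true(all(tb$excessQ >= tb$excessP - 1e-12))
  expect_true(all(tb$consistencyP >= 1 / 301))

  # flipping a member gene's expression flips its kME sign and leaves T
  # unchanged
  v <- exprValues(fx$sim$expr)
  g <- moduleGenes(fx$ms, 3)[1]
  vFlip <- v; vFlip[g, ] <- -vFlip[g, ]
  msFlip <- moduleSetFromAssignments(vFlip, sim <- fx$sim$truth@membership)
  resF <- modDE(msFlip, vFlip, fx$sim$design, contrast,
                nPerm = 300, seed = 13)
  expect_equal(resultTable(resF)$T, tb$T, tolerance = 1e-8)
})

test_that("modDE power is monotone in the coherent shift", {
  deltas <- c(0, 0.5, 1, 2)
  medP <- vapply(deltas, function(d) {
    ps <- vapply(1:3, function(s) {
      cfg <- SynthConfig(nGenes = 600, conditions = c("allo", "allo_dep"),
                        modules = moduleSpec(80, tissue = "epidermis",
                                             effect = 2),
                        perturbModule = 1L, perturbDelta = d,
                        perturbMode = "coherent",
                        perturbCondition = "allo_dep",
                        seed = 7000L + s)
      sim <- generateSynthetic(cfg)
      ms <- moduleSetFromAssignments(sim$expr, sim$truth@membership)
      resultTable(modDE(ms, sim$expr, sim$design,
                        c("condition", "allo_dep", "allo"),
                        nPerm = 500, seed = s))$consistencyP[1]
    }, 0)
    median(ps)
  }, 0)
  expect_true(all(diff(medP) <= 1e-9))
  expect_gt(medP[1], 0.05)   # no shift: null-like
  expect_lt(medP[4], 0.01)   # strong shift: clearly detected
})

test_that("modDE guards tiny designs and absent modules", {
  planted <- tinyPlanted(k = 1, size = 30, nBackground = 10, nSamples = 4,
                         lambda = 0.8, sigma = 0.5, seed = 3)
  d <- tinyDesign(colnames(planted$x), rep("blood", 4),
                  rep(c("a", "b"), each = 2))
  ms <- moduleSetFromAssignments(planted$x, planted$membership)
  expect_error(modDE(ms, planted$x, d, c("condition", "b", "a"),
                     nPerm = 100, seed = 1), "distinct label permutations")

  fx <- moddeFixture("modde_coherent")
  v <- exprValues(fx$sim$expr)
  keep <- setdiff(rownames(v), moduleGenes(fx$ms, 5))
  expect_warning(res <- modDE(fx$ms, v[keep, ], fx$sim$design,
                              c("condition", "allo_dep", "allo"),
                              nPerm = 100, seed = 1), "M5")
  expect_false("M5" %in% resultTable(res)$module)
})

test_that("the trait/modDE join flags the doubly significant module", {
  fx <- moddeFixture("modde_coherent")
  res <- modDE(fx$ms, fx$sim$expr, fx$sim$design,
               c("condition", "allo_dep", "allo"), nPerm = 2000, seed = 5)
  bt <- binaryTraits(fx$sim$design)
  mtm <- moduleTraitMatrix(eigengenes(fx$ms), bt)
  tab <- moddeTraitTable(res, mtm, "tissue_epidermis")
  expect_equal(tab$module[tab$flagged], "M3")
  single <- moddeTraitTable(res, new("ModuleTraitMatrix",
    r = mtm@r["M3", , drop = FALSE], p = mtm@p["M3", , drop = FALSE],
    nSamples = mtm@nSamples), "tissue_epidermis")
  expect_equal(nrow(single), 1L)
  badMtm <- new("ModuleTraitMatrix",
                r = matrix(0, 1, 1, dimnames = list("MX", "t")),
                p = matrix(0.5, 1, 1, dimnames = list("MX", "t")),
                nSamples = 10L)
  expect_error(moddeTraitTable(res, badMtm, "t"), "disjoint")
})
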