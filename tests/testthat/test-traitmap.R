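makeDesign6 <- function() {
  tinyDesign(sprintf("s%02d", 1:6),
             tissues = rep(c("spleen", "pLN", "epidermis"), each = 2),
             conditions = rep(c("syn", "allo"), 3))
}

test_that("binary trait indicators cover tissues, conditions and groups", {
  d <- makeDesign6()
  bt <- binaryTraits(d)
  expect_equal(ncol(bt), 5L)   # 3 tissues + 2 conditions
  expect_equal(sum(bt[, "tissue_spleen"]), 2L)

  bt2 <- binaryTraits(d, grouping = list(SLO = c("spleen", "pLN")))
  expect_equal(unname(bt2[, "group_SLO"]),
               as.integer(d$tissue %in% c("spleen", "pLN")))
  expect_error(binaryTraits(d, grouping = list(SLO = c("spleen", "gill"))),
               "gill")
})

test_that("module-trait correlations match the t oracle and handle edge cases", {
  withr::local_seed(31)
  d <- tinyDesign(sprintf("s%02d", 1:38),
                  tissues = rep(c("blood", "skin"), 19),
                  conditions = rep(c("syn", "allo"), 19))
  bt <- binaryTraits(d)
  # eigengene equal to a (standardized) trait indicator: r = 1
  ind <- bt[, "tissue_blood"]
  me <- rbind(M1 = (ind - mean(ind)) / sd(ind),
              M2 = rnorm(38))
  colnames(me) <- d$sample_id
  mtm <- moduleTraitMatrix(me, bt)
  expect_equal(mtm@r["M1", "tissue_blood"], 1, tolerance = 1e-12)

  # fixed r = 0.5 at n = 38 against the numeric t CDF
  r <- 0.5
  t <- r * sqrt((38 - 2) / (1 - r^2))
  pOracle <- 2 * tUpperOracle(t, 36)
  # construct an eigengene with exactly r = 0.5 to the indicator
  z <- ind - mean(ind); z <- z / sqrt(sum(z^2))
  e <- rnorm(38); e <- e - mean(e)
  e <- e - sum(e * z) * z; e <- e / sqrt(sum(e^2))
  y <- r * z + sqrt(1 - r^2) * e
  me2 <- rbind(M1 = (y - mean(y)) / sd(y))
  colnames(me2) <- d$sample_id
  mtm2 <- moduleTraitMatrix(me2, bt)
  expect_equal(mtm2@r["M1", "tissue_blood"], 0.5, tolerance = 1e-10)
  expect_equal(mtm2@p["M1", "tissue_blood"], pOracle, tolerance = 1e-10)
  expect_equal(negLogP(mtm2)["M1", "tissue_blood"], -log10(pOracle),
               tolerance = 1e-8)

  # constant trait: r = 0, p = 1, with a warning
  btC <- cbind(bt, flat = 1L)
  expect_warning(mtmC <- moduleTraitMatrix(me, btC), "constant")
  expect_equal(unname(mtmC@r[, "flat"]), c(0, 0))
  expect_equal(unname(mtmC@p[, "flat"]), c(1, 1))

  # invariance to sample reordering
  perm <- sample(38)
  mtmP <- moduleTraitMatrix(me[, perm, drop = FALSE], bt)
  expect_equal(mtmP@r, mtm@r, tolerance = 1e-12)
})

test_that("planted tissue-linked module clears the -log10(p) > 2 cutoff", {
  scen <- standardScenarios(101)$recovery
  hits <- vapply(1:10, function(s) {
    scen@seed <- 500L + s
    sim <- generateSynthetic(scen)
    me <- moduleEigengenes(sim$expr, sim$truth@membership)
    bt <- binaryTraits(sim$design)
    mtm <- moduleTraitMatrix(me, bt)
    negLogP(mtm)["M6", "tissue_epidermis"] > 2
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("modules are ranked and classified by their trait pattern", {
  r <- rbind(M1 = c(0.9, -0.2, 0.1), M2 = c(0.3, 0.1, 0.0),
             M3 = c(-0.85, 0.2, 0.3))
  p <- rbind(M1 = c(1e-5, 0.4, 0.6), M2 = c(0.2, 0.7, 0.9),
             M3 = c(1e-4, 0.5, 0.2))
  colnames(r) <- colnames(p) <- c("tissue_blood", "tissue_spleen",
                                  "tissue_epidermis")
  mtm <- new("ModuleTraitMatrix", r = r, p = p, nSamples = 30L)
  rk <- rankModulesByTrait(mtm, "tissue_blood")
  expect_equal(rk$positive, "M1")
  expect_equal(rk$negative, "M3")
  expect_equal(rankModulesByTrait(mtm, "tissue_spleen"),
               list(positive = character(), negative = character()))
  expect_error(rankModulesByTrait(mtm, "tissue_gill"), "unknown trait")

  r2 <- rbind(Ma = c(0.1, 0.2, 0.9, 0.1), Mb = c(0.1, 0.1, 0.8, 0.75),
              Mc = c(0.8, 0.2, 0.85, 0.2), Md = c(0.2, 0.1, 0.2, 0.1))
  p2 <- rbind(Ma = c(0.9, 0.5, 1e-4, 0.8), Mb = c(0.9, 0.8, 1e-3, 2e-3),
              Mc = c(1e-3, 0.4, 1e-4, 0.5), Md = c(0.5, 0.6, 0.4, 0.7))
  colnames(r2) <- colnames(p2) <- c("tissue_spleen", "tissue_pLN",
                                    "tissue_epidermis", "tissue_dermis")
  mtm2 <- new("ModuleTraitMatrix", r = r2, p = p2, nSamples = 30L)
  lab <- classifyModules(mtm2,
    list(SLO = c("tissue_spleen", "tissue_pLN"),
         target = c("tissue_epidermis", "tissue_dermis")))
  expect_equal(unname(lab), c("tissue_specific", "group_selective",
                              "bridging", "unassociated"))
  expect_error(classifyModules(mtm2, list(SLO = "tissue_gill",
                                          target = "tissue_dermis")),
               "unknown trait")
})

test_that("the eigengene network reflects pairwise correlation structure", {
  withr::local_seed(17)
  base <- rnorm(20)
  me <- rbind(M1 = base, M2 = base, M3 = -base + rnorm(20, sd = 1e-8))
  colnames(me) <- sprintf("s%02d", 1:20)
  en <- eigengeneNetwork(me)
  expect_equal(en@adjacency["M1", "M2"], 1, tolerance = 1e-12)
  expect_equal(en@adjacency["M1", "M3"], 0, tolerance = 1e-10)
  expect_equal(nrow(en@edges), 3L)
  expect_error(eigengeneNetwork(me[1, , drop = FALSE]), "2 modules")
})

test_that("classical MDS reproduces embeddable geometries", {
  # three pairwise-equidistant samples map to an equilateral triangle
  v <- cbind(s1 = c(1, 0, 0, 0), s2 = c(0, 1, 0, 0), s3 = c(0, 0, 1, 0))
  rownames(v) <- paste0("g", 1:4)
  xy <- classicalMds(v, nDims = 2, topK = 4)
  d <- as.matrix(dist(xy))
  off <- d[upper.tri(d)]
  expect_lt(max(off) - min(off), 1e-9)

  # planar points: recovered pairwise distances match the input
  withr::local_seed(23)
  pts <- matrix(rnorm(8), 4, 2)
  v2 <- t(cbind(pts, matrix(0, 4, 3)))   # 5 "genes", 4 samples in a plane
  dimnames(v2) <- list(paste0("g", 1:5), paste0("s", 1:4))
  xy2 <- classicalMds(v2, nDims = 2, topK = 5)
  expect_equal(as.matrix(dist(xy2)), as.matrix(dist(pts)),
               ignore_attr = TRUE, tolerance = 1e-8)

  # duplicate samples land on identical coordinates
  v3 <- cbind(v, s4 = v[, "s3"])
  xy3 <- classicalMds(v3, nDims = 2, topK = 4)
  expect_equal(unname(xy3["s3", ]), unname(xy3["s4", ]), tolerance = 1e-9)
})
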