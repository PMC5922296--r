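test_that("hypergeometric overlap matches exact enumeration", {
  u <- paste0("g", 1:10)
  res <- hypergeomOverlap(u[1:5], u[c(1:3, 5)], u)
  expect_equal(res$k, 4L)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)   # C(5,4)/C(10,4)
  # symmetric in A and B
  res2 <- hypergeomOverlap(u[c(1:3, 5)], u[1:5], u)
  expect_equal(res2$p, res$p, tolerance = 1e-15)

  # disjoint sets: P[X >= 0] = 1
  expect_equal(hypergeomOverlap(u[1:3], u[4:6], u)$p, 1)
  # maximal overlap of the whole universe is certain
  expect_equal(hypergeomOverlap(u, u, u)$p, 1)
  expect_error(hypergeomOverlap(u[1], u[2], character()), "empty universe")
  # genes outside the universe are dropped with a message
  expect_message(hypergeomOverlap(c(u[1:3], "alien"), u[1:4], u),
                 "dropped")

  # exhaustive enumeration across small universes
  for (N in c(5, 9, 12)) {
    un <- paste0("g", seq_len(N))
    for (a in c(1, N %/% 2, N - 1)) for (b in c(1, N %/% 3 + 1, N - 1)) {
      k <- length(intersect(seq_len(a), seq_len(b)))
      got <- suppressMessages(hypergeomOverlap(un[1:a], un[1:b], un))$p
      expect_equal(got, hyperOracle(N, a, b, k), tolerance = 1e-12)
    }
  }
})

test_that("GSEA enrichment scores equal the running-sum oracle", {
  withr::local_seed(61)
  scores <- setNames(sort(rnorm(100), decreasing = TRUE),
                     sprintf("g%03d", 1:100))
  # strongly positive top genes: set = top 5 gives a large positive ES
  scores[1:5] <- scores[1:5] + 5
  res <- gseaPreranked(scores, names(scores)[1:5], nPerm = 200, seed = 1)
  expect_gt(res$ES, 0.9)
  expect_gt(res$NES, 1)
  expect_lt(res$p, 0.05)

  # oracle equivalence on random sets and scores, both weights
  for (i in 1:5) {
    withr::with_seed(100 + i, {
      sc <- setNames(rnorm(60), sprintf("h%02d", 1:60))
      set <- sample(names(sc), 12)
    })
    ord <- sc[order(-sc, names(sc))]
    hit <- names(ord) %in% set
    for (w in c(0, 1)) {
      got <- gseaPreranked(sc, set, weight = w, nPerm = 10, seed = 1)$ES
      expect_equal(got, esOracle(ord, hit, w), tolerance = 1e-12)
    }
  }

  # whole-list set: documented degenerate convention ES = 1
  expect_equal(gseaPreranked(scores, names(scores), nPerm = 10,
                             seed = 1)$ES, 1)
  expect_error(gseaPreranked(scores, c("absent1", "absent2")), "disjoint")

  # weight 0: invariant to monotone transformation of the scores
  sc2 <- setNames(seq(3, -3, length.out = 50), sprintf("m%02d", 1:50))
  set2 <- names(sc2)[c(2, 5, 9, 20)]
  es1 <- gseaPreranked(sc2, set2, weight = 0, nPerm = 10, seed = 1)$ES
  es2 <- gseaPreranked(exp(sc2), set2, weight = 0, nPerm = 10, seed = 1)$ES
  expect_equal(es1, es2, tolerance = 1e-12)
})

test_that("GSEA ES agrees with the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  withr::local_seed(71)
  sc <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  set <- sample(names(sc), 25)
  ours <- gseaPreranked(sc, set, weight = 1, nPerm = 10, seed = 1)$ES
  ord <- sort(sc, decreasing = TRUE)
  theirs <- fgsea::calcGseaStat(ord, which(names(ord) %in% set),
                                gseaParam = 1)
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("GSEA results are seed-reproducible", {
  withr::local_seed(81)
  sc <- setNames(rnorm(80), sprintf("g%03d", 1:80))
  sets <- list(a = names(sc)[1:10], b = sample(names(sc), 15))
  r1 <- gseaPreranked(sc, sets, nPerm = 100, seed = 42)
  r2 <- gseaPreranked(sc, sets, nPerm = 100, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(r1$q >= 0 & r1$q <= 1))
})

test_that("ssGSEA scores match the per-rank oracle and its invariances", {
  withr::local_seed(91)
  v <- makeExpr(rnorm(20 * 2), 20, 2)
  sets <- list(sA = rownames(v)[c(1, 4, 7, 11)],
               sB = rownames(v)[c(2, 5, 18)])
  sc <- ssgsea(v, sets, normalize = FALSE)
  for (s in 1:2) for (j in 1:2)
    expect_equal(sc[s, j],
                 ssgseaOracle(v[, s], sets[[j]]), tolerance = 1e-12)

  # identical samples give identical scores
  v2 <- cbind(s1 = v[, 1], s2 = v[, 1])
  rownames(v2) <- rownames(v)
  sc2 <- ssgsea(v2, sets)
  expect_equal(sc2[1, ], sc2[2, ], tolerance = 1e-12)

  # a top-expressed set outranks a bottom-expressed set
  ordG <- rownames(v)[order(-v[, 1])]
  sc3 <- ssgsea(v[, 1, drop = FALSE],
                list(top = ordG[1:5], bottom = rev(ordG)[1:5]),
                normalize = FALSE)
  expect_gt(sc3[1, "top"], sc3[1, "bottom"])

  # rank-based: shifting one sample by a constant changes nothing
  v4 <- v; v4[, 2] <- v4[, 2] + 100
  expect_equal(ssgsea(v4, sets), ssgsea(v, sets), tolerance = 1e-12)

  expect_error(ssgsea(v, list(bad = c("nope1", "nope2"))), "no genes")
})

test_that("cross-species module conservation detects the planted module", {
  scen <- standardScenarios(101)$two_species
  sim <- generateSynthetic(scen)
  # ranked list from the second (upper-cased) dataset: epidermis vs blood
  d2 <- traitDesign(sim$expr2)
  de <- geneDE(sim$expr2, d2, c("condition", "allo", "syn"))
  # rank by epidermis-vs-blood difference instead: use tissue contrast
  d2$arm <- ifelse(d2$tissue == "epidermis", "epi",
                   ifelse(d2$tissue == "blood", "blood", NA))
  keep <- !is.na(d2$arm)
  de2 <- geneDE(exprValues(sim$expr2)[, keep], d2[keep, ],
                c("arm", "epi", "blood"))
  ranked <- setNames(de2$z, de2$gene)
  msets <- GeneSetList(list(
    M1 = names(sim$truth@membership)[sim$truth@membership == 1L],
    M2 = names(sim$truth@membership)[sim$truth@membership == 2L]))
  res <- moduleConservationTest(msets, ranked, nPerm = 500, seed = 3)
  m1 <- res[res$set == "M1", ]   # epidermis-linked module
  expect_gt(m1$NES, 1)
  expect_lt(m1$q, 0.25)

  # scrambled mapping: enrichment collapses
  withr::local_seed(33)
  map <- data.frame(from = names(sim$truth@membership),
                    to = sample(toupper(names(sim$truth@membership))))
  resS <- moduleConservationTest(msets, ranked, mappingTable = map,
                                 nPerm = 500, seed = 3)
  expect_lt(median(abs(resS$NES)), 1.5)
  expect_gt(median(resS$p), 0.05)

  # unmappable modules are each skipped with a warning
  emptyMap <- data.frame(from = "none", to = "NONE")
  warns <- capture_warnings(
    resE <- moduleConservationTest(msets, ranked, mappingTable = emptyMap))
  expect_length(warns, 2L)
  expect_equal(nrow(resE), 0L)
})
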