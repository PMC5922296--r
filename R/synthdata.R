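#' @include AllClasses.R dataio.R
NULL

#' Describe a planted module for SynthConfig
#'
#' @param size number of member genes.
#' @param lambda loading range \code{c(lo, hi)}; per-gene loadings are drawn
#'   uniformly from it.
#' @param tissue,condition optional trait link: the module's latent factor
#'   is shifted by \code{effect} in samples matching the given tissue
#'   and/or condition.
#' @param effect trait effect size on the latent (unit-noise) scale.
#' @return one-row data.frame consumed by \code{\link{SynthConfig}}.
#' @export
moduleSpec <- function(size, lambda = c(0.7, 0.9), tissue = NA_character_,
                       condition = NA_character_, effect = 0) {
  data.frame(size = as.integer(size), lambdaLo = lambda[1L],
             lambdaHi = lambda[2L], traitTissue = tissue,
             traitCondition = condition, effect = effect)
}

#' Construct a synthetic-dataset configuration
#'
#' See \linkS4class{SynthConfig} for the generative model. The default
#' sample grid mirrors a multi-tissue effector T cell study: ~10 tissues
#' (blood, spleen, peripheral/mesenteric lymph nodes, bone marrow, liver,
#' gut lamina propria and intraepithelial compartments, dermis, epidermis)
#' x conditions x 3 replicates.
#'
#' @param nGenes total gene count.
#' @param tissues,conditions,replicates sample grid.
#' @param modules data.frame of \code{\link{moduleSpec}} rows.
#' @param perturbModule index of the perturbed module (0 = none).
#' @param perturbDelta latent shift delta.
#' @param perturbMode "none", "coherent" (shift enters through the latent
#'   factor) or "incoherent" (per-gene shifts of matched magnitude
#'   \eqn{\delta \lambda_g} with random signs, leaving the correlation
#'   structure intact while decoupling DE direction from it).
#' @param perturbCondition,perturbTissue the perturbed design cell
#'   (NA tissue = all tissues).
#' @param secondDataset also generate an independent second dataset.
#' @param preserved logical per module: keep membership in dataset 2 (TRUE)
#'   or scramble it onto random background genes (FALSE).
#' @param upperSecond upper-case gene ids in dataset 2 (two-species
#'   surrogate).
#' @param noiseSd per-gene noise sd on the log2 scale.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return A \linkS4class{SynthConfig}.
#' @export
SynthConfig <- function(nGenes = 3000L,
                        tissues = c("blood", "spleen", "pLN", "mLN", "BM",
                                    "liver", "gut_LP", "gut_IEL", "dermis",
                                    "epidermis"),
                        conditions = c("syn", "allo"), replicates = 3L,
                        modules = data.frame(), perturbModule = 0L,
                        perturbDelta = 0, perturbMode = "none",
                        perturbCondition = NA_character_,
                        perturbTissue = NA_character_,
                        secondDataset = FALSE,
                        preserved = rep(TRUE, nrow(modules)),
                        upperSecond = FALSE, noiseSd = 1, seed = 1L) {
  new("SynthConfig", nGenes = as.integer(nGenes), tissues = tissues,
      conditions = conditions, replicates = as.integer(replicates),
      modules = modules, perturbModule = as.integer(perturbModule),
      perturbDelta = perturbDelta, perturbMode = perturbMode,
      perturbCondition = perturbCondition, perturbTissue = perturbTissue,
      secondDataset = secondDataset, preserved = preserved,
      upperSecond = upperSecond, noiseSd = noiseSd,
      seed = as.integer(seed))
}

sampleGrid <- function(config) {
  g <- expand.grid(replicate = seq_len(config@replicates),
                   condition = config@conditions, tissue = config@tissues,
                   stringsAsFactors = FALSE)
  data.frame(sample_id = paste(g$tissue, g$condition, g$replicate,
                               sep = "_"),
             tissue = g$tissue, condition = g$condition,
             replicate = g$replicate, stringsAsFactors = FALSE)
}

# Latent factors (module x sample) for one dataset: unit Gaussian noise
# plus trait effects, plus the coherent perturbation shift when requested.
drawFactors <- function(config, design, withPerturbation) {
  k <- nrow(config@modules)
  f <- matrix(rnorm(k * nrow(design)), k, nrow(design),
              dimnames = list(paste0("M", seq_len(k)), design$sample_id))
  for (m in seq_len(k)) {
    sp <- config@modules[m, ]
    ind <- rep(TRUE, nrow(design))
    if (!is.na(sp$traitTissue)) ind <- ind & design$tissue == sp$traitTissue
    if (!is.na(sp$traitCondition))
      ind <- ind & design$condition == sp$traitCondition
    if (!is.na(sp$traitTissue) || !is.na(sp$traitCondition))
      f[m, ind] <- f[m, ind] + sp$effect
  }
  if (withPerturbation && config@perturbMode == "coherent" &&
      config@perturbModule > 0L) {
    pind <- perturbedSamples(config, design)
    f[config@perturbModule, pind] <- f[config@perturbModule, pind] +
      config@perturbDelta
  }
  f
}

perturbedSamples <- function(config, design) {
  ind <- design$condition == config@perturbCondition
  if (!is.na(config@perturbTissue))
    ind <- ind & design$tissue == config@perturbTissue
  ind
}

# Assemble the expression matrix from memberships, loadings and factors.
mixExpression <- function(config, membership, loadings, factors, design,
                          withPerturbation, geneSigns = NULL) {
  n <- length(membership); nS <- nrow(design)
  x <- matrix(rnorm(n * nS, sd = config@noiseSd), n, nS,
              dimnames = list(names(membership), design$sample_id))
  for (m in seq_len(nrow(config@modules))) {
    g <- which(membership == m)
    if (length(g))
      x[g, ] <- x[g, ] + outer(loadings[g], factors[m, ])
  }
  if (withPerturbation && config@perturbMode == "incoherent" &&
      config@perturbModule > 0L && !is.null(geneSigns)) {
    pind <- perturbedSamples(config, design)
    g <- names(geneSigns)
    x[g, pind] <- x[g, pind] +
      config@perturbDelta * loadings[g] * geneSigns
  }
  x
}

#' Generate a synthetic multi-tissue expression study
#'
#' Draws one (optionally two) gene x sample expression dataset(s) with
#' planted coexpression modules whose latent factors are tied to
#' tissue/condition indicators, an optional coherent or incoherent
#' perturbation, and per-module preservation or membership scrambling in
#' the second dataset. Fully reproducible from \code{config@seed}.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return list with \code{expr} (\linkS4class{ExpressionDataset} with the
#'   trait design attached), \code{expr2} (second dataset or NULL),
#'   \code{design} (trait data.frame) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @export
generateSynthetic <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  design <- sampleGrid(config)
  k <- nrow(config@modules)
  geneIds <- sprintf("Gene%05d", seq_len(config@nGenes))
  withSeed(config@seed, {
    membership <- setNames(integer(config@nGenes), geneIds)
    pos <- 1L
    for (m in seq_len(k)) {
      sz <- config@modules$size[m]
      membership[pos:(pos + sz - 1L)] <- m
      pos <- pos + sz
    }
    loadings <- setNames(numeric(config@nGenes), geneIds)
    for (m in seq_len(k)) {
      g <- which(membership == m)
      loadings[g] <- runif(length(g), config@modules$lambdaLo[m],
                           config@modules$lambdaHi[m])
    }
    geneSigns <- NULL
    if (config@perturbMode == "incoherent" && config@perturbModule > 0L) {
      g <- names(membership)[membership == config@perturbModule]
      geneSigns <- setNames(sample(c(-1, 1), length(g), replace = TRUE), g)
    }
    f1 <- drawFactors(config, design, withPerturbation = TRUE)
    x1 <- mixExpression(config, membership, loadings, f1, design,
                        withPerturbation = TRUE, geneSigns = geneSigns)
    expr2 <- NULL
    membership2 <- integer(0)
    if (config@secondDataset) {
      membership2 <- setNames(integer(config@nGenes), geneIds)
      pool <- names(membership)[membership == 0L]
      loadings2 <- setNames(numeric(config@nGenes), geneIds)
      for (m in seq_len(k)) {
        if (config@preserved[m]) {
          g <- names(membership)[membership == m]
        } else {
          g <- sample(pool, config@modules$size[m])
          pool <- setdiff(pool, g)
        }
        membership2[g] <- m
        loadings2[g] <- if (config@preserved[m]) loadings[g]
          else unname(loadings[membership == m])[seq_along(g)]
      }
      design2 <- design
      design2$sample_id <- paste0(design$sample_id, "_d2")
      f2 <- drawFactors(config, design2, withPerturbation = FALSE)
      x2 <- mixExpression(config, membership2, loadings2, f2, design2,
                          withPerturbation = FALSE)
      if (config@upperSecond) rownames(x2) <- toupper(rownames(x2))
      expr2 <- ExpressionDataset(
        x2, datasetLabel = "dataset2",
        traits = design2)
    }
  })
  truth <- new("SyntheticTruth", membership = membership,
               loadings = loadings, factors = f1,
               traitEffects = cbind(module = paste0("M", seq_len(k)),
                                    config@modules[, c("traitTissue",
                                                       "traitCondition",
                                                       "effect")]),
               perturbation = list(
                 module = config@perturbModule,
                 delta = config@perturbDelta,
                 mode = config@perturbMode,
                 samples = design$sample_id[
                   if (config@perturbModule > 0L)
                     perturbedSamples(config, design) else logical(0)],
                 geneSigns = geneSigns),
               membership2 = membership2,
               preserved = config@preserved, config = config)
  list(expr = ExpressionDataset(x1, datasetLabel = "dataset1",
                                traits = design),
       expr2 = expr2, design = design, truth = truth)
}

#' Standard validation scenarios
#'
#' Named preset configurations exercising the pipeline end to end:
#' \describe{
#'   \item{recovery}{3000 genes, 6 tissue-linked modules of 50-200 genes,
#'     loadings in [0.7, 0.9], 10 tissues x 2 conditions x 3 replicates
#'     (60 samples): the module-detection benchmark.}
#'   \item{null}{as recovery but with all trait effects 0: calibration.}
#'   \item{preservation}{two datasets; modules 1-4 preserved, modules 5-6
#'     membership-scrambled in dataset 2.}
#'   \item{modde_coherent}{a depletion-style contrast (allo vs allo_dep)
#'     where the epidermis-linked module's latent factor is shifted by
#'     delta = 1.5 in the depleted arm.}
#'   \item{modde_incoherent}{the magnitude-matched control: every member
#'     gene shifted by \eqn{\delta \lambda_g} with random signs independent
#'     of the module correlation structure.}
#'   \item{two_species}{a preserved second dataset carrying upper-cased
#'     gene symbols, for orthology-mapped conservation tests.}
#' }
#'
#' @param seed base seed; each preset derives its own documented offset.
#' @return named list of \linkS4class{SynthConfig}.
#' @export
standardScenarios <- function(seed = 101L) {
  seed <- as.integer(seed)
  sixModules <- function(effect = 2) rbind(
    moduleSpec(200, tissue = "blood", effect = effect),
    moduleSpec(170, tissue = "spleen", effect = effect),
    moduleSpec(140, tissue = "pLN", effect = effect),
    moduleSpec(110, tissue = "liver", effect = effect),
    moduleSpec(80, tissue = "dermis", effect = effect),
    moduleSpec(50, tissue = "epidermis", effect = effect))
  moddeModules <- rbind(
    moduleSpec(150, tissue = "blood", effect = 2),
    moduleSpec(120, tissue = "spleen", effect = 2),
    moduleSpec(100, tissue = "epidermis", effect = 2),
    moduleSpec(80, tissue = "dermis", effect = 2),
    moduleSpec(60, tissue = "liver", effect = 2))
  list(
    recovery = SynthConfig(nGenes = 3000L, modules = sixModules(2),
                           seed = seed),
    null = SynthConfig(nGenes = 3000L, modules = sixModules(0),
                       seed = seed + 1L),
    preservation = SynthConfig(
      nGenes = 1500L,
      modules = rbind(moduleSpec(150, tissue = "blood", effect = 2),
                      moduleSpec(120, tissue = "spleen", effect = 2),
                      moduleSpec(100, tissue = "epidermis", effect = 2),
                      moduleSpec(100, tissue = "liver", effect = 2),
                      moduleSpec(80, tissue = "dermis", effect = 2),
                      moduleSpec(60, tissue = "gut_LP", effect = 2)),
      secondDataset = TRUE,
      preserved = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
      seed = seed + 2L),
    modde_coherent = SynthConfig(
      nGenes = 1500L, conditions = c("allo", "allo_dep"),
      modules = moddeModules, perturbModule = 3L, perturbDelta = 1.5,
      perturbMode = "coherent", perturbCondition = "allo_dep",
      seed = seed + 3L),
    modde_incoherent = SynthConfig(
      nGenes = 1500L, conditions = c("allo", "allo_dep"),
      modules = moddeModules, perturbModule = 3L, perturbDelta = 1.5,
      perturbMode = "incoherent", perturbCondition = "allo_dep",
      seed = seed + 4L),
    two_species = SynthConfig(
      nGenes = 1200L,
      modules = rbind(moduleSpec(150, tissue = "epidermis", effect = 2),
                      moduleSpec(120, tissue = "blood", effect = 2),
                      moduleSpec(100, tissue = "spleen", effect = 2),
                      moduleSpec(80, tissue = "liver", effect = 2)),
      secondDataset = TRUE, preserved = rep(TRUE, 4L),
      upperSecond = TRUE, seed = seed + 5L))
}
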