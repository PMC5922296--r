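#' @include AllClasses.R dataio.R modules.R traitmap.R preservation.R
#' @include modde.R enrichment.R synthdata.R
NULL

#' Read a pipeline run configuration
#'
#' Stage functions (\code{\link{cmdNet}} and friends) take a plain named
#' list; this reads one from YAML. Recognized top-level fields: \code{paths}
#' (expression, traits, expression2, assignments, eigengenes, gmt, mapping,
#' ranked), \code{outdir}, \code{seed}, \code{network}, \code{filter},
#' \code{grouping}, \code{preservation}, \code{modde}, \code{enrichment},
#' \code{simulate}.
#'
#' @param path YAML file.
#' @return named list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

# Validate shared config fields; returns the config with defaults filled.
validateRunConfig <- function(config, needPaths = character()) {
  if (is.null(config$outdir)) stop("config$outdir is required")
  for (p in needPaths) {
    f <- config$paths[[p]]
    if (is.null(f)) stop("config$paths$", p, " is required")
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  if (!is.null(config$seed) &&
      config$seed != as.integer(config$seed))
    stop("seed must be an integer")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  config
}

# Stage provenance manifest: parameters, seed, package version and input
# hashes, sufficient to re-execute the stage exactly.
writeManifest <- function(config, stage, params, inputs) {
  files <- unlist(inputs)
  if (is.null(files)) files <- character(0)
  manifest <- list(stage = stage, params = params,
                   seed = config$seed,
                   package = as.character(packageVersion("coexmod")),
                   inputs = as.list(tools::md5sum(files)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(config$outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

writeStageTsv <- function(df, path, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# coexmod stage=", stage,
                    " version=", packageVersion("coexmod")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readStageTsv <- function(path)
  read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)

moduleLabels <- function(k, style = c("numeric", "letters")) {
  style <- match.arg(style)
  if (style == "numeric") paste0("M", seq_len(k))
  else paste0("M", LETTERS[seq_len(k)])
}

#' Network stage: detect modules and write assignment/eigengene/kME tables
#'
#' Reads expression and traits, applies optional gene filtering, picks the
#' soft power (or uses the configured one), detects modules, and writes
#' \code{module_assignments.tsv}, \code{eigengenes.tsv}, \code{kme.tsv},
#' \code{modules.gmt} and a JSON run manifest to \code{config$outdir}.
#' Module ids are ordered by descending size and labeled M1..Mk
#' (\code{network$labelStyle = "letters"} gives MA..Mk for a second
#' dataset's modules).
#'
#' @param config run configuration list (see \code{\link{readRunConfig}}).
#' @return the \linkS4class{ModuleSet}, invisibly.
#' @export
cmdNet <- function(config) {
  config <- validateRunConfig(config, c("expression", "traits"))
  net <- config$network
  expr <- readExpressionTsv(config$paths$expression)
  traits <- readTraitsTsv(config$paths$traits, expr)
  expr <- attachTraits(expr, traits)
  if (!is.null(config$filter)) {
    exclude <- if (!is.null(config$filter$excludeFile))
      readLines(config$filter$excludeFile) else character()
    expr <- filterGenes(expr, exclude, config$filter$topK)
  }
  power <- if (is.null(net$power)) "auto" else net$power
  ms <- detectModules(expr, power = power,
                      mode = net$mode %||% "signed_hybrid",
                      minSize = net$minSize %||% 30L,
                      cutHeight = net$cutHeight %||% 0.995,
                      deepSplit = net$deepSplit %||% 2L,
                      mergeThreshold = net$mergeThreshold %||% 0.25,
                      kmeCut = net$kmeCut %||% 0.4,
                      seed = config$seed)
  labels <- moduleLabels(nModules(ms), net$labelStyle %||% "numeric")
  a <- moduleAssignments(ms)
  lab <- c("M0", labels)[a + 1L]
  ownKme <- rep(NA_real_, length(a))
  ownKme[a > 0L] <- ms@kme[cbind(which(a > 0L), a[a > 0L])]
  writeStageTsv(data.frame(gene = names(a), module = lab, kme = ownKme),
                file.path(config$outdir, "module_assignments.tsv"), "net")
  me <- eigengenes(ms); rownames(me) <- labels
  writeStageTsv(data.frame(module = rownames(me), me,
                           check.names = FALSE),
                file.path(config$outdir, "eigengenes.tsv"), "net")
  km <- ms@kme; colnames(km) <- labels
  writeStageTsv(data.frame(gene = rownames(km), km, check.names = FALSE),
                file.path(config$outdir, "kme.tsv"), "net")
  if (nModules(ms) > 0) {
    gs <- moduleGeneSets(ms)
    names(gs@sets) <- labels; names(gs@descriptions) <- labels
    writeGmt(gs, file.path(config$outdir, "modules.gmt"))
  }
  writeManifest(config, "net",
                c(ms@parameters, labelStyle = net$labelStyle %||% "numeric"),
                config$paths[c("expression", "traits")])
  invisible(ms)
}

#' Trait stage: module-trait correlation table
#'
#' @param config run configuration with \code{paths$eigengenes},
#'   \code{paths$expression}, \code{paths$traits} and optional
#'   \code{grouping} (named list of tissue groups).
#' @return the \linkS4class{ModuleTraitMatrix}, invisibly.
#' @export
cmdTraits <- function(config) {
  config <- validateRunConfig(config,
                              c("eigengenes", "expression", "traits"))
  expr <- readExpressionTsv(config$paths$expression)
  traits <- readTraitsTsv(config$paths$traits, expr)
  meTab <- readStageTsv(config$paths$eigengenes)
  me <- as.matrix(meTab[, -1, drop = FALSE])
  rownames(me) <- meTab[[1L]]
  ind <- binaryTraits(traits, config$grouping %||% list())
  mtm <- moduleTraitMatrix(me, ind)
  long <- expand.grid(module = rownames(mtm@r), trait = colnames(mtm@r),
                      stringsAsFactors = FALSE)
  long$r <- mtm@r[as.matrix(long[, 1:2])]
  long$p <- mtm@p[as.matrix(long[, 1:2])]
  long$neglog10p <- -log10(long$p)
  writeStageTsv(long, file.path(config$outdir, "module_trait.tsv"),
                "traits")
  writeManifest(config, "traits", list(grouping = config$grouping),
                config$paths[c("eigengenes", "expression", "traits")])
  invisible(mtm)
}

readAssignments <- function(path) {
  tb <- readStageTsv(path)
  suf <- sub("^M", "", tb$module)
  a <- suppressWarnings(as.integer(suf))
  a[is.na(a)] <- match(suf[is.na(a)], LETTERS)
  if (anyNA(a)) stop("unparseable module label(s) in ", path)
  setNames(a, tb$gene)
}

#' Preservation stage: cross-dataset module preservation table
#'
#' @param config run configuration with \code{paths$expression} (reference),
#'   \code{paths$expression2} (test), \code{paths$assignments}, and
#'   \code{preservation$nPerm} (> 0), \code{seed}.
#' @return the \linkS4class{PreservationResult}, invisibly.
#' @export
cmdPreserve <- function(config) {
  config <- validateRunConfig(config,
    c("expression", "expression2", "assignments"))
  nPerm <- config$preservation$nPerm %||% 200L
  if (nPerm < 1L) stop("preservation$nPerm must be positive")
  ref <- readExpressionTsv(config$paths$expression)
  test <- readExpressionTsv(config$paths$expression2)
  assign <- readAssignments(config$paths$assignments)
  ms <- moduleSetFromAssignments(ref, assign)
  pres <- modulePreservation(ref, test, ms,
    power = config$network$power %||% 6L,
    mode = config$network$mode %||% "signed_hybrid",
    nPerm = nPerm, seed = config$seed)
  tb <- resultTable(pres)
  tb$label <- classifyPreservation(pres)
  writeStageTsv(tb, file.path(config$outdir, "preservation.tsv"),
                "preserve")
  writeManifest(config, "preserve", list(nPerm = nPerm),
                config$paths[c("expression", "expression2", "assignments")])
  invisible(pres)
}

#' modDE stage: module-level differential expression table
#'
#' @param config run configuration with \code{paths$expression},
#'   \code{paths$traits}, \code{paths$assignments} and \code{modde} options
#'   (contrast = c(variable, groupB, groupA), nPerm, alpha0), \code{seed}.
#' @return the \linkS4class{ModDEResult}, invisibly.
#' @export
cmdModde <- function(config) {
  config <- validateRunConfig(config,
                              c("expression", "traits", "assignments"))
  if (is.null(config$modde$contrast))
    stop("modde$contrast is required (variable, groupB, groupA)")
  expr <- readExpressionTsv(config$paths$expression)
  traits <- readTraitsTsv(config$paths$traits, expr)
  assign <- readAssignments(config$paths$assignments)
  ms <- moduleSetFromAssignments(expr, assign)
  res <- modDE(ms, expr, traits, unlist(config$modde$contrast),
               nPerm = config$modde$nPerm %||% 10000L,
               seed = config$seed,
               alpha0 = config$modde$alpha0 %||% 0.05)
  writeStageTsv(resultTable(res),
                file.path(config$outdir, "modde.tsv"), "modde")
  writeManifest(config, "modde", config$modde,
                config$paths[c("expression", "traits", "assignments")])
  invisible(res)
}

#' Enrichment stage: ssGSEA and/or preranked GSEA tables
#'
#' Runs single-sample GSEA of the configured gene sets over the expression
#' samples, and preranked GSEA when a ranked list file (TSV: gene, score)
#' is configured. Gene sets sharing no genes with the data are skipped with
#' a warning; it is an error only if all are skipped.
#'
#' @param config run configuration with \code{paths$expression},
#'   \code{paths$gmt}, optional \code{paths$ranked}, \code{enrichment}
#'   options (alpha, weight, nPerm), \code{seed}.
#' @return list of result tables, invisibly.
#' @export
cmdEnrich <- function(config) {
  config <- validateRunConfig(config, c("expression", "gmt"))
  expr <- readExpressionTsv(config$paths$expression)
  gs <- readGmt(config$paths$gmt)
  usable <- vapply(gs@sets, function(s)
    length(intersect(s, geneIds(expr))) > 0L, TRUE)
  for (nm in names(gs@sets)[!usable])
    warning("gene set '", nm, "' shares no genes with the data; skipped")
  if (!any(usable)) stop("all configured gene sets are absent from the data")
  gsUse <- GeneSetList(gs@sets[usable], gs@descriptions[usable])
  out <- list()
  sc <- ssgsea(expr, gsUse, alpha = config$enrichment$alpha %||% 0.25)
  scoresTab <- data.frame(sample = rownames(sc), sc, check.names = FALSE)
  writeStageTsv(scoresTab, file.path(config$outdir, "ssgsea.tsv"),
                "enrich")
  out$ssgsea <- scoresTab
  if (!is.null(config$paths$ranked)) {
    rk <- readStageTsv(config$paths$ranked)
    scores <- setNames(as.numeric(rk[[2L]]), rk[[1L]])
    out$gsea <- gseaPreranked(scores, gsUse,
                              weight = config$enrichment$weight %||% 1,
                              nPerm = config$enrichment$nPerm %||% 1000L,
                              seed = config$seed)
    writeStageTsv(out$gsea, file.path(config$outdir, "gsea.tsv"),
                  "enrich")
  }
  writeManifest(config, "enrich", config$enrichment,
                config$paths[c("expression", "gmt")])
  invisible(out)
}

#' Simulate stage: write a standard synthetic scenario to disk
#'
#' @param config run configuration with \code{simulate$scenario} (one of
#'   \code{\link{standardScenarios}}), \code{outdir} and optional
#'   \code{seed} overriding the preset seed.
#' @return the generated list (see \code{\link{generateSynthetic}}),
#'   invisibly.
#' @export
cmdSimulate <- function(config) {
  config <- validateRunConfig(config)
  name <- config$simulate$scenario
  scen <- standardScenarios(config$simulate$baseSeed %||% 101L)
  if (is.null(name) || !name %in% names(scen))
    stop("simulate$scenario must be one of: ",
         paste(names(scen), collapse = ", "))
  cfg <- scen[[name]]
  if (!is.null(config$seed)) cfg@seed <- as.integer(config$seed)
  sim <- generateSynthetic(cfg)
  writeExpressionTsv(sim$expr,
                     file.path(config$outdir, "expression.tsv"))
  writeTraitsTsv(sim$design, file.path(config$outdir, "traits.tsv"))
  if (!is.null(sim$expr2))
    writeExpressionTsv(sim$expr2,
                       file.path(config$outdir, "expression2.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(scenario = name, seed = cfg@seed,
         membership = as.list(truth@membership),
         loadings = as.list(truth@loadings),
         preserved = truth@preserved,
         perturbation = truth@perturbation[
           c("module", "delta", "mode", "samples")]),
    file.path(config$outdir, "truth.json"), auto_unbox = TRUE)
  writeManifest(config, "simulate", list(scenario = name, seed = cfg@seed),
                list())
  invisible(sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
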