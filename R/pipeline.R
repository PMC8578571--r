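#' Assemble a pipeline configuration
#'
#' Exactly one of the synthetic spec or the set of real input paths must be
#' given.  All stage parameters live here; every source of randomness fans
#' out from the single `seed`.
#'
#' @param outputDir directory the stage tables are written to.
#' @param synthetic a [SimulationSpec-class], or NULL for a real-data run.
#' @param expression,design,goSets,pathwaySets,pathwayRelations,geneInteractions
#'   real-input file paths (expression TSV, two-column sample/group TSV,
#'   two GMT collections, two typed edge lists); all NULL for a synthetic
#'   run.
#' @param dialect expression-table dialect for real input.
#' @param nPermutations,s0Strategy,qThreshold,fcThreshold SAM parameters.
#' @param enrichmentFdr,enrichmentP enrichment significance gates
#'   (see [significantSets()]).
#' @param minDegree core/hub degree cut (default 1).
#' @param seed master seed.
#' @return a validated config list of class `samnetConfig`.
#' @export
pipelineConfig <- function(outputDir,
                           synthetic = simulationSpec(),
                           expression = NULL, design = NULL,
                           goSets = NULL, pathwaySets = NULL,
                           pathwayRelations = NULL, geneInteractions = NULL,
                           dialect = "plain",
                           nPermutations = 1000L,
                           s0Strategy = "cv_minimisation",
                           qThreshold = 0.05, fcThreshold = 1.5,
                           enrichmentFdr = 0.05, enrichmentP = NULL,
                           minDegree = 1L, seed = 1L) {
  real <- list(expression = expression, design = design, goSets = goSets,
               pathwaySets = pathwaySets, pathwayRelations = pathwayRelations,
               geneInteractions = geneInteractions)
  anyReal <- any(!vapply(real, is.null, logical(1)))
  if (anyReal && !is.null(synthetic))
    stop("give either real input paths or a synthetic spec, not both")
  if (!anyReal && is.null(synthetic))
    stop("one of real inputs or a synthetic spec is required")
  if (anyReal && (is.null(expression) || is.null(design)))
    stop("a real-data run needs at least 'expression' and 'design'")
  stopifnot(qThreshold > 0, fcThreshold > 0,
            is.null(enrichmentFdr) || enrichmentFdr > 0,
            is.null(enrichmentP) || enrichmentP > 0, minDegree >= 0)
  cfg <- c(list(outputDir = outputDir, synthetic = synthetic,
                dialect = dialect,
                nPermutations = as.integer(nPermutations),
                s0Strategy = s0Strategy, qThreshold = qThreshold,
                fcThreshold = fcThreshold, enrichmentFdr = enrichmentFdr,
                enrichmentP = enrichmentP, minDegree = as.integer(minDegree),
                seed = as.integer(seed)),
           real)
  class(cfg) <- "samnetConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; a `synthetic:` mapping
#' holds [simulationSpec()] arguments.
#'
#' @param path YAML file path.
#' @return a `samnetConfig` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(simulationSpec, y$synthetic)
  do.call(pipelineConfig, y)
}

# deterministic table writer: comment header (parameters, seed, version)
# then a plain TSV body
.writeStageTable <- function(df, path, cfg, extra = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# samnet ", as.character(packageVersion("samnet"))),
    paste0("# seed: ", cfg$seed),
    paste0("# nPermutations: ", cfg$nPermutations,
           " | qThreshold: ", cfg$qThreshold,
           " | fcThreshold: ", cfg$fcThreshold,
           " | enrichmentFdr: ", ifelse(is.null(cfg$enrichmentFdr), "NULL",
                                        cfg$enrichmentFdr),
           " | minDegree: ", cfg$minDegree),
    extra), con)
  write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stage order is fixed: normalization, SAM differential expression,
#' over-representation against the GO-like and pathway-like collections,
#' the pathway-interaction network with core-pathway ranking, then the
#' gene signal network with hub ranking.  Each stage table is written with
#' a comment header recording seed, parameters and package version, so a
#' rerun under the same config is byte-identical.
#'
#' @param config a `samnetConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return a manifest list: `files` (the seven stage tables), `counts`
#'   (genes, DEGs up/down, significant sets, core pathways, hub genes) and,
#'   for synthetic runs, `planted` (truth table, planted set id, planted
#'   bridge/hub ids).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "samnetConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  planted <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## ingest -----------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec@seed <- config$seed
    sim <- stage("simulate", simulateExpression(spec))
    expr <- sim$expr
    truth <- sim$truth
    nDe <- sum(truth$planted != "none")
    plantedSz <- function(target)  # fit the planted sets to the DE pool
      max(4L, min(target, floor(nDe / 0.9)))
    # a primary strongly enriched set plus weaker secondaries, so the
    # significant list (and hence the pathway network) has realistic depth
    sets1 <- stage("simulate", simulateGeneSets(truth, nSets = 80,
      setSize = c(10, 100), plantedSize = plantedSz(50L),
      plantedFraction = c(0.9, rep(0.5, 4)), seed = config$seed + 1L))
    sets2 <- stage("simulate", simulateGeneSets(truth, nSets = 60,
      setSize = c(10, 80), plantedSize = plantedSz(40L),
      plantedFraction = c(0.9, rep(0.5, 7)), seed = config$seed + 2L))
    pathwayRelations <- NULL   # simulated once the significant set is known
    planted <- list(truth = truth, goSet = sets1$plantedId,
                    pathwaySet = sets2$plantedId)
    goColl <- sets1$collection
    pwColl <- sets2$collection
    geneInteractions <- NULL   # built after the DEGs are known
  } else {
    designTab <- read.delim(config$design, header = TRUE,
                            stringsAsFactors = FALSE)
    groups <- stats::setNames(designTab[[2L]], designTab[[1L]])
    expr <- stage("ingest", readExpressionTable(
      config$expression, dialect = config$dialect, groups = groups))
    goColl <- if (!is.null(config$goSets))
      stage("ingest", readGmt(config$goSets, rownames(expr)))
    pwColl <- if (!is.null(config$pathwaySets))
      stage("ingest", readGmt(config$pathwaySets, rownames(expr)))
    pathwayRelations <- if (!is.null(config$pathwayRelations))
      stage("ingest", readEdgeList(config$pathwayRelations))
    geneInteractions <- if (!is.null(config$geneInteractions))
      stage("ingest", readEdgeList(config$geneInteractions))
  }

  ## normalize + SAM --------------------------------------------------------
  expr <- stage("normalize", quantileNormalize(expr))
  fit <- stage("sam", samFit(expr,
    nPermutations = config$nPermutations, s0Strategy = config$s0Strategy,
    seed = config$seed, qThreshold = config$qThreshold,
    fcThreshold = config$fcThreshold))
  degs <- callDEGs(fit)
  files <- c(degs = file.path(config$outputDir, "degs.tsv"))
  degOut <- degs$table[, c("gene", "d", "fold_change", "p", "q",
                           "regulation", "rank")]
  colnames(degOut) <- c("gene", "d_score", "fold_change", "p", "q",
                        "feature", "rank")
  degOut$feature <- ifelse(degOut$feature == "up", "Up", "Down")
  .writeStageTable(degOut, files["degs"], config,
                   paste0("# s0: ", format(fit@s0, digits = 15),
                          " | pi0: ", format(fit@piZero, digits = 15)))

  ## enrichment -------------------------------------------------------------
  degIds <- degs$table$gene
  if (!length(degIds)) stop("stage 'enrichment' failed: no DEGs called")
  enrGo <- stage("enrichment", fisherEnrich(degIds, goColl))
  enrPw <- stage("enrichment", fisherEnrich(degIds, pwColl))
  sigGo <- significantSets(enrGo, config$enrichmentFdr, config$enrichmentP)
  sigPw <- significantSets(enrPw, config$enrichmentFdr, config$enrichmentP)
  files["enrichment_go"] <- file.path(config$outputDir, "enrichment_go.tsv")
  files["enrichment_pathway"] <-
    file.path(config$outputDir, "enrichment_pathway.tsv")
  .writeStageTable(sigGo, files["enrichment_go"], config)
  .writeStageTable(sigPw, files["enrichment_pathway"], config)

  ## pathway network --------------------------------------------------------
  if (!nrow(sigPw)) stop("stage 'pathway_network' failed: no significant pathways")
  if (is.null(pathwayRelations) && !is.null(config$synthetic)) {
    # synthetic relation catalogue over the significant pathways, with the
    # top-ranked pathway as the designated high-degree node
    if (nrow(sigPw) >= 4L) {
      relSim <- simulateRelationGraph(nrow(sigPw), style = "pathway",
                                      seed = config$seed + 3L,
                                      nodeIds = sigPw$set_id)
      pathwayRelations <- graphEdges(relSim$graph)
      planted$pathwayHub <- relSim$manifest$hub
    } else {
      # too few pathways for a random graph: a simple chain
      pathwayRelations <- if (nrow(sigPw) >= 2L)
        data.frame(from = sigPw$set_id[-nrow(sigPw)],
                   to = sigPw$set_id[-1L], type = "link", directed = TRUE)
    }
  }
  pwFeatures <- stats::setNames(
    pathwayFeature(sigPw$members_hit, degs$table), sigPw$set_id)
  pwNames <- stats::setNames(sigPw$name, sigPw$set_id)
  pwNet <- stage("pathway_network", buildPathwayNetwork(
    sigPw$set_id, pathwayRelations, names = pwNames, features = pwFeatures))
  pwCent <- centralityTable(pwNet)
  corePw <- coreFilter(pwCent, config$minDegree, orderBy = "degree")
  files["pathway_network"] <- file.path(config$outputDir,
                                        "pathway_network.tsv")
  files["core_pathways"] <- file.path(config$outputDir, "core_pathways.tsv")
  writeEdgeList(pwNet, files["pathway_network"])
  .writeStageTable(
    corePw[, c("id", "name", "outdegree", "indegree", "degree",
               "feature", "rank")],
    files["core_pathways"], config)

  ## gene network -----------------------------------------------------------
  if (is.null(geneInteractions) && !is.null(config$synthetic)) {
    # interactions over the called DEGs plus a margin of non-DEGs, so the
    # induced-subgraph restriction is exercised
    reg <- samResults(fit)
    nonDeg <- setdiff(reg$gene, degIds)
    netGenes <- .withSeed(config$seed + 4L, {
      c(head(degIds, 40L), sample(nonDeg, min(10L, length(nonDeg))))
    })
    geneSim <- simulateRelationGraph(length(netGenes), style = "gene",
                                     seed = config$seed + 5L,
                                     nodeIds = netGenes)
    geneInteractions <- graphEdges(geneSim$graph)
    planted$geneBridge <- geneSim$manifest$bridge
  }
  geneNet <- stage("gene_network",
    buildGeneNetwork(degs$table, geneInteractions))
  geneCent <- centralityTable(geneNet)
  hubs <- coreFilter(geneCent, config$minDegree, orderBy = "betweenness")
  files["gene_network"] <- file.path(config$outputDir, "gene_network.tsv")
  files["hub_genes"] <- file.path(config$outputDir, "hub_genes.tsv")
  writeEdgeList(geneNet, files["gene_network"])
  .writeStageTable(
    hubs[, c("id", "feature", "betweenness", "indegree", "outdegree",
             "degree", "rank")],
    files["hub_genes"], config)

  list(files = files,
       counts = list(genes = nrow(samResults(fit)),
                     degs = nrow(degs$table),
                     up = nrow(degs$up), down = nrow(degs$down),
                     significant_go = nrow(sigGo),
                     significant_pathways = nrow(sigPw),
                     core_pathways = nrow(corePw),
                     hub_genes = nrow(hubs)),
       fit = fit, planted = planted)
}

#' Volcano-plot data export
#'
#' One row per gene: x is the signed fold change, y is `-log10(p)` (finite
#' by the add-one permutation p), and `call` flags the regulation
#' (`up`/`down`/`none`), so called-down genes sit left of the midline and
#' called-up genes right of it.
#'
#' @param fit a [SamFit-class].
#' @return data.frame with columns `gene`, `fold_change`, `neg_log10_p`,
#'   `call`.
#' @export
volcanoData <- function(fit) {
  res <- samResults(fit)
  data.frame(gene = res$gene, fold_change = res$fold_change,
             neg_log10_p = -log10(res$p), call = res$regulation,
             stringsAsFactors = FALSE)
}

#' Dendrogram data export for a DEG heatmap
#'
#' Standardises each gene row to zero mean and unit variance
#' (constant rows to zero), clusters genes and samples by average-linkage
#' hierarchical clustering on Euclidean distance, and serialises both
#' linkage tables in merge order.  Deterministic for a fixed input.
#'
#' @param x an [ExpressionExperiment-class].
#' @param genes the DEG ids to cluster (at least 2).
#' @param method linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return list with `geneLinkage` and `sampleLinkage` (data.frames with
#'   columns `merge1`, `merge2`, `height`; negative entries index leaves),
#'   `geneOrder` and `sampleOrder` (leaf orders), and `genes`, `samples`.
#' @export
dendrogramData <- function(x, genes, method = "average") {
  stopifnot(methods::is(x, "ExpressionExperiment"))
  missing <- setdiff(genes, rownames(x))
  if (length(missing)) stop("unknown feature id: ", missing[1L])
  if (length(genes) < 2L) stop("at least 2 genes are required")
  m <- exprsValues(x)[genes, , drop = FALSE]
  z <- t(apply(m, 1L, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  linkTable <- function(h) data.frame(merge1 = h$merge[, 1L],
                                      merge2 = h$merge[, 2L],
                                      height = h$height)
  hg <- hclust(dist(z), method = method)
  hs <- hclust(dist(t(z)), method = method)
  list(geneLinkage = linkTable(hg), sampleLinkage = linkTable(hs),
       geneOrder = hg$order, sampleOrder = hs$order,
       genes = genes, samples = colnames(m))
}

#' Relative expression by the 2^-ddCt method
#'
#' `fold = 2^-dddCt` with `ddCt = (Ct_target,case - Ct_ref,case) -
#' (Ct_target,control - Ct_ref,control)`: the qRT-PCR convention for
#' expression of a target gene relative to a housekeeping gene, case
#' versus control.
#'
#' @param ctTargetCase,ctRefCase,ctTargetCtrl,ctRefCtrl Ct cycle numbers.
#' @return the relative fold (vectorised).
#' @export
ddctFold <- function(ctTargetCase, ctRefCase, ctTargetCtrl, ctRefCtrl) {
  ddct <- (ctTargetCase - ctRefCase) - (ctTargetCtrl - ctRefCtrl)
  2^(-ddct)
}
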