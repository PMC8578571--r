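#' Create a simulation specification
#'
#' Defaults emulate the motivating two-group soleus-muscle design: 6 arrays
#' per group, 15,000 features, planted down/up fractions 4.8%/1.4% (echoing
#' a roughly 720:205 down:up imbalance), a planted absolute effect of 1.5
#' log2 units and within-group SD 0.25 log2 units on a Gaussian
#' log2-intensity baseline (mean 8, SD 2).
#'
#' @param nGenes,nPerGroup,fracDown,fracUp,effectLog2,sigma numeric
#'   parameters, see [SimulationSpec-class].
#' @param baselineMean,baselineSd baseline log2-intensity distribution.
#' @param seed integer RNG seed.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(nGenes = 15000, nPerGroup = 6,
                           fracDown = 0.048, fracUp = 0.014,
                           effectLog2 = 1.5, sigma = 0.25,
                           baselineMean = 8, baselineSd = 2, seed = 1) {
  methods::new("SimulationSpec",
    nGenes = as.integer(nGenes), nPerGroup = as.integer(nPerGroup),
    fracDown = fracDown, fracUp = fracUp, effectLog2 = effectLog2,
    sigma = sigma, baselineMean = baselineMean, baselineSd = baselineSd,
    seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec: %d genes, %d vs %d | down %.1f%%, up %.1f%% | effect %.2f log2, sigma %.2f | seed %d\n",
    object@nGenes, object@nPerGroup, object@nPerGroup,
    100 * object@fracDown, 100 * object@fracUp,
    object@effectLog2, object@sigma, object@seed))
})

#' Simulate a two-group expression experiment with planted effects
#'
#' Gene baselines are drawn from `Normal(baselineMean, baselineSd)`;
#' control samples from `Normal(mu_g, sigma)`; experimental samples from
#' `Normal(mu_g - effect, sigma)` for planted down genes,
#' `Normal(mu_g + effect, sigma)` for planted up genes, and `Normal(mu_g,
#' sigma)` otherwise.  Group variances are equal and noise is Gaussian on
#' the log2 scale.  Fully deterministic for a fixed spec.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with `expr` (an [ExpressionExperiment-class], log2 scale,
#'   design set) and `truth` (`DataFrame` of `gene`, `planted` in
#'   `down`/`up`/`none`).
#' @export
simulateExpression <- function(spec) {
  stopifnot(methods::is(spec, "SimulationSpec"))
  methods::validObject(spec)
  G <- spec@nGenes; k <- spec@nPerGroup
  nDown <- round(G * spec@fracDown); nUp <- round(G * spec@fracUp)
  genes <- sprintf("G%05d", seq_len(G))
  samples <- c(sprintf("ctrl_%d", seq_len(k)), sprintf("expt_%d", seq_len(k)))
  out <- .withSeed(spec@seed, {
    planted <- rep("none", G)
    de <- sample.int(G, nDown + nUp)
    planted[de[seq_len(nDown)]] <- "down"
    if (nUp > 0) planted[de[nDown + seq_len(nUp)]] <- "up"
    mu <- rnorm(G, spec@baselineMean, spec@baselineSd)
    shift <- ifelse(planted == "down", -spec@effectLog2,
                    ifelse(planted == "up", spec@effectLog2, 0))
    vals <- cbind(
      matrix(rnorm(G * k, mu, spec@sigma), G, k),
      matrix(rnorm(G * k, mu + shift, spec@sigma), G, k))
    list(vals = vals, planted = planted)
  })
  dimnames(out$vals) <- list(genes, samples)
  expr <- ExpressionExperiment(out$vals,
    groups = rep(c("control", "experimental"), each = k), scale = "log2")
  truth <- S4Vectors::DataFrame(gene = genes, planted = out$planted)
  rownames(truth) <- genes
  list(expr = expr, truth = truth)
}

#' Simulate gene-set collections with one planted enriched set
#'
#' Background sets are uniform random draws from the universe; one
#' designated set is filled to `plantedFraction` with planted
#' differentially expressed genes (taken from the truth table), the
#' remainder with non-DE genes, so over-representation analysis must rank
#' it first when DE recovery works.
#'
#' @param truth truth table from [simulateExpression()].
#' @param nSets number of sets including the designated ones.
#' @param setSize integer range `c(min, max)` of background set sizes.
#' @param plantedSize size of each designated set.
#' @param plantedFraction fraction(s) of the designated set(s) drawn from
#'   planted DE genes; a vector plants one set per element (the first is
#'   the primary, strongest set).  0 makes a designated set
#'   indistinguishable from background.
#' @param seed integer RNG seed.
#' @return list with `collection` (a [GeneSetCollection-class]),
#'   `plantedId` (the primary designated set's id) and `plantedIds` (all
#'   designated ids, in `plantedFraction` order).
#' @export
simulateGeneSets <- function(truth, nSets = 100, setSize = c(10, 100),
                             plantedSize = 50, plantedFraction = 0.8,
                             seed = 1) {
  universe <- as.character(truth$gene)
  deGenes <- universe[truth$planted != "none"]
  nDesignated <- length(plantedFraction)
  stopifnot(nDesignated >= 1L, nSets > nDesignated)
  nPlantedMembers <- round(plantedSize * plantedFraction)
  if (any(nPlantedMembers > length(deGenes)))
    stop("plantedFraction requires ", max(nPlantedMembers),
         " DE genes but only ", length(deGenes), " are planted")
  sets <- .withSeed(seed, {
    sizes <- sample(setSize[1L]:setSize[2L], nSets - nDesignated,
                    replace = TRUE)
    bg <- lapply(sizes, function(sz) sample(universe, sz))
    designated <- lapply(nPlantedMembers, function(nm) {
      forced <- sample(deGenes, nm)
      # remainder from the whole remaining universe, so a plantedFraction
      # of 0 makes the designated set a plain background draw
      c(forced, sample(setdiff(universe, forced), plantedSize - nm))
    })
    c(bg, designated)
  })
  ids <- sprintf("SET%04d", seq_len(nSets))
  names(sets) <- ids
  plantedIds <- ids[nSets - nDesignated + seq_len(nDesignated)]
  list(collection = GeneSetCollection(sets, universe),
       plantedId = plantedIds[1L], plantedIds = plantedIds)
}

#' Simulate a typed relation graph with planted structure
#'
#' `pathway` style: a sparse random directed graph with one designated
#' high-degree node guaranteed to have maximal degree.  `gene` style: two
#' dense clusters joined through a single bridge node, giving the bridge
#' the strictly largest betweenness; edge types are drawn from the KEGG
#' legend and a fraction of clique edges is written as reciprocal directed
#' arcs so the edge set genuinely mixes directed and undirected relations.
#'
#' @param nNodes number of nodes (at least 4).
#' @param style `"pathway"` or `"gene"`.
#' @param seed integer RNG seed.
#' @param nodeIds optional node ids (defaults to `P001..`/`N001..`).
#' @param edgeProb pathway style: arc probability among non-hub nodes.
#' @return list with `graph` (a [RelationGraph-class]) and `manifest`
#'   naming the planted `hub` (pathway) or `bridge` (gene) node.
#' @export
simulateRelationGraph <- function(nNodes, style = c("pathway", "gene"),
                                  seed = 1, nodeIds = NULL,
                                  edgeProb = 0.08) {
  style <- match.arg(style)
  if (nNodes < 4) stop("nNodes must be at least 4")
  if (is.null(nodeIds))
    nodeIds <- sprintf(if (style == "pathway") "P%03d" else "N%03d",
                       seq_len(nNodes))
  stopifnot(length(nodeIds) == nNodes, !anyDuplicated(nodeIds))
  if (style == "pathway") {
    out <- .withSeed(seed, {
      hub <- nodeIds[1L]
      others <- nodeIds[-1L]
      pairs <- expand.grid(from = others, to = others,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
      pairs <- pairs[runif(nrow(pairs)) < edgeProb, , drop = FALSE]
      # hub arcs: enough out- and in-neighbours to dominate every degree
      nOut <- max(2L, ceiling(length(others) * 0.5))
      nIn <- max(1L, ceiling(length(others) * 0.25))
      hubEdges <- data.frame(
        from = c(rep(hub, nOut), sample(others, nIn)),
        to = c(sample(others, nOut), rep(hub, nIn)))
      ed <- rbind(hubEdges, pairs)
      ed$type <- "link"
      ed$directed <- TRUE
      list(hub = hub, edges = ed)
    })
    g <- relationGraph(nodeIds, out$edges)
    # construction guarantee: top up hub arcs until its degree is maximal
    deg <- nodeDegrees(g)
    while (max(deg$degree[deg$id != out$hub]) > deg$degree[deg$id == out$hub]) {
      edg <- graphEdges(g)
      missingOut <- setdiff(nodeIds[-1L], edg$to[edg$from == out$hub])
      missingIn <- setdiff(nodeIds[-1L], edg$from[edg$to == out$hub])
      if (length(missingOut))
        extra <- data.frame(from = out$hub, to = missingOut[1L],
                            type = "link", directed = TRUE)
      else if (length(missingIn))
        extra <- data.frame(from = missingIn[1L], to = out$hub,
                            type = "link", directed = TRUE)
      else break  # hub fully connected: its degree 2(n-1) is the maximum
      g <- relationGraph(nodeIds, rbind(edg, extra))
      deg <- nodeDegrees(g)
    }
    list(graph = g, manifest = list(hub = out$hub))
  } else {
    half <- (nNodes - 1L) %/% 2L
    bridge <- nodeIds[1L]
    clusterA <- nodeIds[1L + seq_len(half)]
    clusterB <- nodeIds[(1L + half + 1L):nNodes]
    clique <- function(members) {
      if (length(members) < 2L)
        return(data.frame(from = character(), to = character()))
      cmb <- combn(members, 2L)
      data.frame(from = cmb[1L, ], to = cmb[2L, ])
    }
    # two attachment points per cluster (when available): the bridge then
    # carries every cross-cluster shortest path in full while each gateway
    # node only collects fractional credit, so the bridge's betweenness is
    # strictly maximal whatever the cluster-size split
    gates <- c(head(clusterA, 2L), head(clusterB, 2L))
    ed <- rbind(clique(clusterA), clique(clusterB),
                data.frame(from = bridge, to = gates))
    ed <- .withSeed(seed, {
      ed$type <- sample(c("c", "a", "ind", "inh", "ex", "b"),
                        nrow(ed), replace = TRUE)
      ed$directed <- FALSE
      # rewrite a fraction of clique edges as reciprocal directed arcs;
      # the adjacency view (hence all shortest paths) is unchanged
      recip <- which(ed$from != bridge & runif(nrow(ed)) < 0.3)
      if (length(recip)) {
        back <- ed[recip, , drop = FALSE]
        back[, c("from", "to")] <- back[, c("to", "from")]
        ed$directed[recip] <- TRUE
        back$directed <- TRUE
        ed <- rbind(ed, back)
      }
      ed
    })
    g <- relationGraph(nodeIds, ed)
    list(graph = g, manifest = list(bridge = bridge,
                                    clusterA = clusterA, clusterB = clusterB))
  }
}
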