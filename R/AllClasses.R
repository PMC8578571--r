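#' Two-group expression experiment
#'
#' An `ExpressionExperiment` is a [SummarizedExperiment::SummarizedExperiment]
#' holding one `exprs` assay of feature-by-sample intensities together with a
#' scale flag (`"linear"` or `"log2"`).  The two-group design lives in
#' `colData(x)$group`, a factor with levels `control` and `experimental`.
#'
#' @slot scaleFlag character, `"linear"` or `"log2"`.
#' @export
setClass("ExpressionExperiment",
  contains = "SummarizedExperiment",
  slots = c(scaleFlag = "character"),
  prototype = prototype(scaleFlag = "log2")
)

setValidity("ExpressionExperiment", function(object) {
  msg <- character()
  if (length(object@scaleFlag) != 1L ||
      !object@scaleFlag %in% c("linear", "log2"))
    msg <- c(msg, "scaleFlag must be one of 'linear', 'log2'")
  if (length(SummarizedExperiment::assayNames(object)) &&
      !"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  rn <- rownames(object); cn <- colnames(object)
  if (anyDuplicated(rn))
    msg <- c(msg, paste0("duplicated feature id: ", rn[duplicated(rn)][1L]))
  if (anyDuplicated(cn))
    msg <- c(msg, paste0("duplicated sample id: ", cn[duplicated(cn)][1L]))
  if (nrow(object) && ncol(object)) {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v)) msg <- c(msg, "exprs assay must be numeric")
    else if (!all(is.finite(v))) msg <- c(msg, "exprs values must be finite")
  }
  if ("group" %in% colnames(SummarizedExperiment::colData(object))) {
    g <- SummarizedExperiment::colData(object)$group
    if (!is.factor(g) || !identical(levels(g), c("control", "experimental")))
      msg <- c(msg, "group must be a factor with levels control, experimental")
    else if (anyNA(g)) msg <- c(msg, "every sample must be assigned a group")
    else if (ncol(object) && any(table(g) == 0L))
      msg <- c(msg, "both groups must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' SAM differential-expression fit
#'
#' Per-gene SAM statistics, permutation p-values, q-values and regulation
#' calls, plus the parameters that produced them.
#'
#' @slot results a `DataFrame` with columns `gene`, `r`, `s`, `d`,
#'   `fold_change`, `p`, `q`, `regulation`, `rank`.
#' @slot s0 the fudge factor used in the d statistic.
#' @slot piZero estimated proportion of null genes.
#' @slot nAssignments number of group relabellings in the null.
#' @slot enumerated whether the null enumerated every distinct relabelling.
#' @slot nullPoolSize total number of pooled null d values.
#' @slot seed integer seed used when the null was sampled.
#' @slot qThreshold,fcThreshold the calling thresholds.
#' @export
setClass("SamFit",
  slots = c(
    results = "DataFrame", s0 = "numeric", piZero = "numeric",
    nAssignments = "integer", enumerated = "logical",
    nullPoolSize = "numeric", seed = "integer",
    qThreshold = "numeric", fcThreshold = "numeric"
  )
)

setValidity("SamFit", function(object) {
  need <- c("gene", "r", "s", "d", "fold_change", "p", "q",
            "regulation", "rank")
  if (!all(need %in% colnames(object@results)))
    return(paste("results must contain:", paste(need, collapse = ", ")))
  res <- object@results
  if (nrow(res)) {
    if (any(res$s < 0)) return("s must be non-negative")
    bad <- abs(res$d - res$r / (res$s + object@s0)) > 1e-12
    if (any(bad)) return("d must equal r/(s + s0)")
    o <- order(-abs(res$d))
    if (is.unsorted(res$q[o])) return("q must be non-decreasing in decreasing |d|")
  }
  TRUE
})

#' Gene-set collection
#'
#' Named member lists over a fixed gene universe; members are restricted to
#' the universe on construction and empty sets are dropped (with a message).
#'
#' @slot sets named list of character vectors of member gene ids.
#' @slot setDescriptions named character vector of display names.
#' @slot universe character vector of background gene ids.
#' @export
setClass("GeneSetCollection",
  slots = c(sets = "list", setDescriptions = "character",
            universe = "character")
)

setValidity("GeneSetCollection", function(object) {
  if (anyDuplicated(names(object@sets))) return("set ids must be unique")
  if (anyDuplicated(object@universe)) return("universe ids must be unique")
  if (!all(unlist(object@sets, use.names = FALSE) %in% object@universe))
    return("set members must lie in the universe")
  if (any(lengths(object@sets) == 0L)) return("empty sets are not allowed")
  TRUE
})

#' Typed relation graph
#'
#' A mixed directed/undirected graph of typed relations (pathway-pathway or
#' gene-gene).  Undirected edges are stored once and expanded to both
#' directions in the adjacency view used for degrees, shortest paths and
#' betweenness.
#'
#' @slot nodes `DataFrame` with columns `id`, `name`, `feature`.
#' @slot edges data.frame with columns `from`, `to`, `type`,
#'   `directed` (logical).  Types follow the KEGG-style legend: compound
#'   `c`, activation `a`, indirect `ind`, inhibition `inh`, expression `ex`,
#'   binding `b`, or the generic pathway `link`.
#' @export
setClass("RelationGraph",
  slots = c(nodes = "DataFrame", edges = "data.frame")
)

.EDGE_TYPES <- c("c", "a", "ind", "inh", "ex", "b", "link")

setValidity("RelationGraph", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("id", "name", "feature") %in% colnames(nd)))
    return("nodes needs columns id, name, feature")
  if (anyDuplicated(nd$id)) return("node ids must be unique")
  if (nrow(ed)) {
    if (!all(c("from", "to", "type", "directed") %in% colnames(ed)))
      return("edges needs columns from, to, type, directed")
    if (!all(c(ed$from, ed$to) %in% nd$id))
      return("edge endpoints must be nodes")
    if (!is.logical(ed$directed)) return("edges$directed must be logical")
    if (!all(ed$type %in% .EDGE_TYPES))
      return(paste("edge types must be in:", paste(.EDGE_TYPES, collapse = " ")))
    if (any(ed$from == ed$to)) return("self-loops are not allowed")
  }
  TRUE
})

#' Simulation specification for the synthetic two-group study
#'
#' Defaults emulate the shape of the motivating study: 12 soleus-muscle
#' arrays in two balanced groups of 6, tens of thousands of features, and a
#' planted down:up imbalance of roughly 720:205 differential genes
#' (4.8% down, 1.4% up of 15,000 features).
#'
#' @slot nGenes number of features (default 15000).
#' @slot nPerGroup samples per group (default 6).
#' @slot fracDown,fracUp planted fractions of down-/up-regulated genes.
#' @slot effectLog2 planted absolute log2 effect (default 1.5).
#' @slot sigma within-group SD in log2 units (default 0.25).
#' @slot baselineMean,baselineSd parameters of the Gaussian baseline
#'   log2-intensity distribution.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationSpec",
  slots = c(
    nGenes = "integer", nPerGroup = "integer",
    fracDown = "numeric", fracUp = "numeric",
    effectLog2 = "numeric", sigma = "numeric",
    baselineMean = "numeric", baselineSd = "numeric", seed = "integer"
  ),
  prototype = prototype(
    nGenes = 15000L, nPerGroup = 6L, fracDown = 0.048, fracUp = 0.014,
    effectLog2 = 1.5, sigma = 0.25, baselineMean = 8, baselineSd = 2,
    seed = 1L
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be at least 2")
  if (object@fracDown < 0 || object@fracUp < 0 ||
      object@fracDown + object@fracUp >= 1)
    msg <- c(msg, "planted fractions must be in [0,1) and sum below 1")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (object@effectLog2 < 0) msg <- c(msg, "effectLog2 must be non-negative")
  if (length(msg)) msg else TRUE
})
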