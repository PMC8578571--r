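#' Construct a typed relation graph
#'
#' Self-loops and exact duplicate edges are dropped with a message.  Node
#' `name`/`feature` default to the id and `""`.
#'
#' @param nodes character vector of node ids, or a data.frame/`DataFrame`
#'   with columns `id` and optionally `name`, `feature`.
#' @param edges data.frame with columns `from`, `to`, `type` (one of
#'   `c a ind inh ex b link`) and `directed` (logical or 0/1).
#' @return a [RelationGraph-class].
#' @export
relationGraph <- function(nodes, edges = NULL) {
  if (is.character(nodes)) nodes <- data.frame(id = nodes)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"name" %in% colnames(nodes)) nodes$name <- nodes$id
  if (!"feature" %in% colnames(nodes)) nodes$feature <- ""
  nd <- S4Vectors::DataFrame(id = as.character(nodes$id),
                             name = as.character(nodes$name),
                             feature = as.character(nodes$feature))
  rownames(nd) <- nd$id
  if (is.null(edges) || !nrow(edges)) {
    ed <- data.frame(from = character(), to = character(),
                     type = character(), directed = logical())
  } else {
    ed <- data.frame(from = as.character(edges$from),
                     to = as.character(edges$to),
                     type = as.character(edges$type),
                     directed = as.logical(edges$directed),
                     stringsAsFactors = FALSE)
    loops <- ed$from == ed$to
    if (any(loops)) {
      message(sum(loops), " self-loop(s) dropped")
      ed <- ed[!loops, , drop = FALSE]
    }
    # an undirected edge is one object whichever way it is written
    key <- ifelse(ed$directed, paste(ed$from, ed$to, ed$type, "d"),
                  paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to),
                        ed$type, "u"))
    dup <- duplicated(key)
    if (any(dup)) {
      message(sum(dup), " duplicate edge(s) dropped")
      ed <- ed[!dup, , drop = FALSE]
    }
    rownames(ed) <- NULL
  }
  methods::new("RelationGraph", nodes = nd, edges = ed)
}

#' @describeIn relationGraph the node table.
#' @param g a `RelationGraph`.
#' @export
graphNodes <- function(g) g@nodes

#' @describeIn relationGraph the edge table.
#' @export
graphEdges <- function(g) g@edges

setMethod("show", "RelationGraph", function(object) {
  ed <- object@edges
  cat("RelationGraph:", nrow(object@nodes), "nodes,", nrow(ed), "edges (",
      sum(ed$directed), "directed,", sum(!ed$directed), "undirected )\n")
})

#' Adjacency view of a relation graph
#'
#' Directed edges become one arc; undirected edges expand to both
#' directions.  Parallel arcs of different types collapse: the view is the
#' 0/1 adjacency the degree and shortest-path computations use.
#'
#' @param g a [RelationGraph-class].
#' @return data.frame of unique arcs with columns `from`, `to`.
#' @export
adjacencyArcs <- function(g) {
  ed <- graphEdges(g)
  if (!nrow(ed))
    return(data.frame(from = character(), to = character()))
  arcs <- rbind(ed[, c("from", "to")],
                data.frame(from = ed$to[!ed$directed],
                           to = ed$from[!ed$directed]))
  arcs <- arcs[!duplicated(paste(arcs$from, arcs$to)), , drop = FALSE]
  rownames(arcs) <- NULL
  arcs
}

#' Node degrees on the adjacency view
#'
#' Indegree counts upstream neighbours, outdegree downstream neighbours;
#' an undirected edge contributes 1 to both at each endpoint, and
#' `degree = indegree + outdegree` always.
#'
#' @param g a [RelationGraph-class].
#' @return `DataFrame` with columns `id`, `indegree`, `outdegree`, `degree`,
#'   one row per node.
#' @export
nodeDegrees <- function(g) {
  ids <- graphNodes(g)$id
  arcs <- adjacencyArcs(g)
  indeg <- table(factor(arcs$to, levels = ids))
  outdeg <- table(factor(arcs$from, levels = ids))
  S4Vectors::DataFrame(id = ids,
                       indegree = as.integer(indeg),
                       outdegree = as.integer(outdeg),
                       degree = as.integer(indeg) + as.integer(outdeg))
}

# Brandes (2001) accumulation for unweighted directed graphs.
# adj: list of integer out-neighbour vectors; returns raw ordered-pair
# betweenness (endpoints excluded, fractional credit on tied paths).
.brandes <- function(adj, n) {
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    stack <- integer(0)
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      stack <- c(stack, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(stack)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc
}

#' Betweenness centrality on the adjacency view
#'
#' Unnormalised betweenness `B(i) = sum over ordered pairs (s, t), s != i
#' != t, of sigma_st(i) / sigma_st`, where `sigma_st` counts shortest paths
#' from s to t on the directed adjacency view (undirected edges usable both
#' ways), with unit edge weights, endpoints excluded, fractional credit
#' when several shortest paths tie, and disconnected pairs contributing 0.
#' Edge types are annotation only: inhibition and indirect edges are
#' traversable like any other.
#'
#' @param g a [RelationGraph-class].
#' @return named numeric vector of betweenness values, one per node.
#' @export
nodeBetweenness <- function(g) {
  ids <- graphNodes(g)$id
  n <- length(ids)
  arcs <- adjacencyArcs(g)
  adj <- rep(list(integer(0)), n)
  if (nrow(arcs)) {
    fi <- match(arcs$from, ids); ti <- match(arcs$to, ids)
    sp <- split(ti, fi)
    adj[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  stats::setNames(.brandes(adj, n), ids)
}

#' Full centrality table for a relation graph
#'
#' @param g a [RelationGraph-class].
#' @return `DataFrame` with `id`, `name`, `feature`, `indegree`,
#'   `outdegree`, `degree`, `betweenness`.
#' @export
centralityTable <- function(g) {
  deg <- nodeDegrees(g)
  bt <- nodeBetweenness(g)
  nd <- graphNodes(g)
  out <- S4Vectors::DataFrame(
    id = deg$id, name = nd$name, feature = nd$feature,
    indegree = deg$indegree, outdegree = deg$outdegree,
    degree = deg$degree, betweenness = unname(bt[deg$id]))
  rownames(out) <- out$id
  out
}

#' Filter to core nodes and order the table
#'
#' Core pathways and hub genes are the nodes with `degree >= minDegree`
#' (default 1, i.e. non-isolated).  Pathway tables are ordered by
#' decreasing degree, gene tables by decreasing betweenness; ties break by
#' the other criterion, then by id.
#'
#' @param records a centrality `DataFrame` (see [centralityTable()]).
#' @param minDegree minimum degree kept (default 1).
#' @param orderBy `"degree"` (pathway convention) or `"betweenness"`
#'   (gene convention).
#' @return the filtered table with a `rank` column 1..n.
#' @export
coreFilter <- function(records, minDegree = 1L,
                       orderBy = c("degree", "betweenness")) {
  orderBy <- match.arg(orderBy)
  out <- records[records$degree >= minDegree, , drop = FALSE]
  ord <- if (orderBy == "degree")
    order(-out$degree, -out$betweenness, out$id)
  else order(-out$betweenness, -out$degree, out$id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Rank hub nodes by betweenness
#'
#' Descending betweenness, ties by descending degree then id; the top-k
#' prefix is returned with ranks 1..k.
#'
#' @param records a centrality `DataFrame`.
#' @param topK number of hubs to return; values beyond the node count
#'   return the whole ranked list.
#' @return the ranked prefix.
#' @export
rankHubs <- function(records, topK = nrow(records)) {
  if (topK <= 0) stop("topK must be positive")
  ord <- order(-records$betweenness, -records$degree, records$id)
  out <- records[ord, , drop = FALSE]
  out <- head(out, topK)
  out$rank <- seq_len(nrow(out))
  out
}

#' Build the pathway-interaction network
#'
#' The induced subgraph of the relation edge list on the significant
#' pathways only; relations touching any non-significant or unknown
#' pathway are skipped (counted in a message).  Directed edges keep the
#' relation file's upstream-to-downstream orientation.  Significant
#' pathways with no surviving relation stay as isolated nodes.
#'
#' @param significant character vector of significant pathway ids.
#' @param relations relation edge list (`from`, `to`, `type`, `directed`),
#'   e.g. from [readEdgeList()].
#' @param names optional named character vector of display names.
#' @param features optional named character vector of up/down features
#'   (see [pathwayFeature()]).
#' @return a [RelationGraph-class].
#' @export
buildPathwayNetwork <- function(significant, relations, names = NULL,
                                features = NULL) {
  significant <- unique(as.character(significant))
  if (!length(significant)) stop("no significant pathways")
  nodes <- data.frame(id = significant)
  if (!is.null(names)) nodes$name <- unname(names[significant])
  if (!is.null(features)) nodes$feature <- unname(features[significant])
  if (is.null(relations) || !nrow(relations)) {
    return(relationGraph(nodes))
  }
  keep <- relations$from %in% significant & relations$to %in% significant
  if (any(!keep))
    message(sum(!keep), " relation(s) outside the significant set skipped")
  relationGraph(nodes, relations[keep, , drop = FALSE])
}

#' Build the gene signal network
#'
#' The induced subgraph of the typed gene-interaction edge list on the
#' DEGs; interactions touching non-DEG or unknown genes are skipped
#' (counted in a message).  Node features carry the regulation call
#' (`Up`/`Down`).
#'
#' @param degTable a called-DEG table with columns `gene` and `regulation`
#'   (see [callDEGs()]`$table`), or a named character vector of
#'   `"up"`/`"down"` by gene id.
#' @param interactions gene-interaction edge list (`from`, `to`, `type`,
#'   `directed`).
#' @return a [RelationGraph-class].
#' @export
buildGeneNetwork <- function(degTable, interactions) {
  if (is.character(degTable)) {
    genes <- names(degTable); regulation <- unname(degTable)
  } else {
    genes <- as.character(degTable$gene)
    regulation <- as.character(degTable$regulation)
  }
  if (!length(genes)) stop("no DEGs")
  feature <- ifelse(tolower(regulation) == "up", "Up", "Down")
  nodes <- data.frame(id = genes, name = genes, feature = feature)
  if (is.null(interactions) || !nrow(interactions))
    return(relationGraph(nodes))
  keep <- interactions$from %in% genes & interactions$to %in% genes
  if (any(!keep))
    message(sum(!keep), " interaction(s) outside the DEG set skipped")
  relationGraph(nodes, interactions[keep, , drop = FALSE])
}

#' Up/down feature of a pathway from its member DEGs
#'
#' A pathway whose hit members are all down-regulated is `Down`, all up is
#' `Up`; mixed pathways are labelled with the majority direction first
#' (`Down|up` or `Up|down`; equal counts give `Down|up`).
#'
#' @param membersHit pipe-delimited member string(s) from [fisherEnrich()].
#' @param degTable called-DEG table with `gene` and `regulation`.
#' @return character vector of features.
#' @export
pathwayFeature <- function(membersHit, degTable) {
  reg <- stats::setNames(tolower(as.character(degTable$regulation)),
                         as.character(degTable$gene))
  vapply(membersHit, function(mh) {
    genes <- strsplit(mh, "|", fixed = TRUE)[[1L]]
    r <- reg[genes[genes %in% names(reg)]]
    nUp <- sum(r == "up"); nDown <- sum(r == "down")
    if (nUp == 0L && nDown == 0L) ""
    else if (nUp == 0L) "Down"
    else if (nDown == 0L) "Up"
    else if (nUp > nDown) "Up|down" else "Down|up"
  }, character(1), USE.NAMES = FALSE)
}

#' Read a typed edge list from TSV
#'
#' Columns: `source <tab> target <tab> type <tab> directed` (0/1), with a
#' header row.
#'
#' @param path file path.
#' @return data.frame with columns `from`, `to`, `type`, `directed`.
#' @export
readEdgeList <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 4L) stop("edge list needs source, target, type, directed")
  out <- data.frame(from = as.character(tab[[1L]]),
                    to = as.character(tab[[2L]]),
                    type = as.character(tab[[3L]]),
                    directed = as.logical(as.integer(tab[[4L]])))
  bad <- setdiff(out$type, .EDGE_TYPES)
  if (length(bad)) stop("unknown edge type: ", bad[1L])
  out
}

#' Write a typed edge list (and optional node table) as TSV
#'
#' @param g a [RelationGraph-class].
#' @param path edge-list output path.
#' @param nodePath optional node-table output path.
#' @export
writeEdgeList <- function(g, path, nodePath = NULL) {
  ed <- graphEdges(g)
  out <- data.frame(source = ed$from, target = ed$to, type = ed$type,
                    directed = as.integer(ed$directed))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nodePath))
    write.table(as.data.frame(graphNodes(g)), nodePath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
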