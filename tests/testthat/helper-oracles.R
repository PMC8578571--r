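# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops, mean()/sum() arithmetic, and (for
# betweenness) explicit shortest-path enumeration through igraph.

# small log2-scale experiment with a balanced design
makeExpr <- function(values, nCtrl = ncol(values) / 2) {
  groups <- rep(c("control", "experimental"),
                c(nCtrl, ncol(values) - nCtrl))
  ExpressionExperiment(values, groups = groups, scale = "log2")
}

randomMatrix <- function(nGenes, nSamples, seed, mean = 8, sd = 1) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples, mean, sd), nGenes, nSamples,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("s%02d", seq_len(nSamples))))
}

# per-gene d statistic written out longhand
oracleD <- function(x, ctrlIdx, s0) {
  n <- length(x)
  exptIdx <- setdiff(seq_len(n), ctrlIdx)
  x1 <- x[ctrlIdx]; x2 <- x[exptIdx]
  r <- mean(x2) - mean(x1)
  ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  s <- sqrt((1 / length(x1) + 1 / length(x2)) *
              ss / (length(x1) + length(x2) - 2))
  r / (s + s0)
}

# pooled two-sided permutation p over every label assignment, by loops
oraclePermP <- function(m, nCtrl, s0) {
  assigns <- combn(ncol(m), nCtrl)
  pool <- numeric(0)
  for (b in seq_len(ncol(assigns)))
    for (gIdx in seq_len(nrow(m)))
      pool <- c(pool, oracleD(m[gIdx, ], assigns[, b], s0))
  dObs <- vapply(seq_len(nrow(m)), function(gIdx)
    oracleD(m[gIdx, ], seq_len(nCtrl), s0), numeric(1))
  p <- vapply(dObs, function(d)
    (1 + sum(abs(pool) >= abs(d))) / (1 + length(pool)), numeric(1))
  list(d = dObs, p = p)
}

# min-over-thresholds q recomputation by double loop (mirrors the stated
# construction, not the package's vectorised implementation)
oracleQ <- function(dObs, dNull) {
  absObs <- abs(dObs)
  absNull <- abs(dNull)
  d50 <- median(as.numeric(absNull))
  piZero <- min(1, sum(absObs <= d50) / (sum(absNull <= d50) / ncol(dNull)))
  fdrAt <- function(thr) {
    O <- sum(absObs >= thr)
    Fexp <- median(apply(absNull, 2, function(col) sum(col >= thr)))
    min(1, piZero * Fexp / max(O, 1))
  }
  vapply(absObs, function(dg) {
    thr <- absObs[absObs <= dg]
    min(vapply(thr, fdrAt, numeric(1)))
  }, numeric(1))
}

# exact upper-tail enrichment probabilities by draw enumeration:
# returns P[overlap >= k] for every k, for a set of size K, n draws from N
oracleEnrichTail <- function(N, K, n) {
  draws <- combn(N, n)
  overlaps <- colSums(draws <= K)  # the set is 1..K
  vapply(0:min(K, n), function(k) mean(overlaps >= k), numeric(1))
}

# betweenness by explicit enumeration of all shortest paths (igraph)
oracleBetweenness <- function(g) {
  ids <- graphNodes(g)$id
  arcs <- adjacencyArcs(g)
  ig <- igraph::graph_from_data_frame(arcs, directed = TRUE, vertices = ids)
  bc <- setNames(numeric(length(ids)), ids)
  for (s in ids) for (t in ids) {
    if (s == t) next
    paths <- suppressWarnings(
      igraph::all_shortest_paths(ig, from = s, to = t, mode = "out"))$vpaths
    if (!length(paths)) next
    sigma <- length(paths)
    for (pth in paths) {
      inner <- setdiff(names(pth), c(s, t))
      bc[inner] <- bc[inner] + 1 / sigma
    }
  }
  bc
}

# seeded random mixed directed/undirected typed graph on <= 12 nodes
randomMixedGraph <- function(seed, maxNodes = 12) {
  set.seed(seed)
  n <- sample(4:maxNodes, 1)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < 0.35
  ed <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                   stringsAsFactors = FALSE)
  if (nrow(ed)) {
    flip <- runif(nrow(ed)) < 0.5
    tmp <- ed$from[flip]; ed$from[flip] <- ed$to[flip]; ed$to[flip] <- tmp
    ed$type <- sample(c("c", "a", "ind", "inh", "ex", "b"), nrow(ed),
                      replace = TRUE)
    ed$directed <- runif(nrow(ed)) < 0.5
  } else {
    ed <- NULL
  }
  relationGraph(ids, ed)
}

# stage tables written by runPipeline: comment header then TSV
readStageTable <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
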