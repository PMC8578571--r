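test_that("graph construction cleans self-loops and duplicate edges", {
  ed <- data.frame(from = c("A", "A", "B", "C"),
                   to = c("B", "A", "A", "D"),
                   type = c("c", "a", "c", "inh"),
                   directed = c(FALSE, FALSE, FALSE, TRUE))
  expect_message(expect_message(
    g <- relationGraph(LETTERS[1:4], ed),
    "self-loop"), "duplicate")
  expect_identical(nrow(graphEdges(g)), 2L)  # A-B (B-A is the same edge), C->D
})

test_that("degrees follow the adjacency-view expansion rule", {
  # single undirected edge: both endpoints (1, 1, 2)
  g <- relationGraph(c("A", "B"),
                     data.frame(from = "A", to = "B", type = "c",
                                directed = FALSE))
  deg <- nodeDegrees(g)
  expect_equal(deg$indegree, c(1L, 1L))
  expect_equal(deg$outdegree, c(1L, 1L))
  expect_equal(deg$degree, c(2L, 2L))

  # directed chain A->B->C
  chain <- relationGraph(c("A", "B", "C"),
    data.frame(from = c("A", "B"), to = c("B", "C"),
               type = "link", directed = TRUE))
  dc <- nodeDegrees(chain)
  expect_equal(dc$indegree, c(0L, 1L, 1L))
  expect_equal(dc$outdegree, c(1L, 1L, 0L))

  # isolated node
  iso <- relationGraph("Z")
  expect_equal(as.vector(unlist(nodeDegrees(iso)[, -1])), c(0L, 0L, 0L))
})

test_that("degree = indegree + outdegree and arcs are counted once each", {
  for (seed in 1:10) {
    g <- randomMixedGraph(seed)
    deg <- nodeDegrees(g)
    expect_identical(deg$degree, deg$indegree + deg$outdegree)
    arcs <- adjacencyArcs(g)
    expect_identical(sum(deg$indegree), nrow(arcs))
    expect_identical(sum(deg$outdegree), nrow(arcs))
  }
})

test_that("pathway network is the induced subgraph on significant pathways", {
  rel <- data.frame(from = c("A", "A", "C"), to = c("B", "C", "B"),
                    type = "link", directed = TRUE)
  expect_message(g <- buildPathwayNetwork(c("A", "B"), rel), "2 relation")
  expect_identical(nrow(graphEdges(g)), 1L)
  expect_identical(graphEdges(g)$from, "A")

  # empty relation file: isolated nodes only
  g0 <- buildPathwayNetwork(c("A", "B"), NULL)
  expect_identical(nrow(graphEdges(g0)), 0L)
  expect_identical(nrow(graphNodes(g0)), 2L)
})

test_that("gene network restricts to DEGs and carries regulation features", {
  degs <- c(Acat1 = "down", Hadh = "up")
  inter <- data.frame(from = c("Acat1", "Acat1"), to = c("Hadh", "Cpt1b"),
                      type = c("c", "a"), directed = c(FALSE, TRUE))
  expect_message(g <- buildGeneNetwork(degs, inter), "1 interaction")
  expect_identical(nrow(graphEdges(g)), 1L)
  expect_identical(graphEdges(g)$type, "c")
  expect_false(graphEdges(g)$directed)
  expect_identical(graphNodes(g)["Acat1", "feature"], "Down")
  expect_identical(graphNodes(g)["Hadh", "feature"], "Up")
})

test_that("betweenness matches hand-computed small cases", {
  # directed path A->B->C: only B mediates, one ordered pair
  chain <- relationGraph(c("A", "B", "C"),
    data.frame(from = c("A", "B"), to = c("B", "C"),
               type = "link", directed = TRUE))
  expect_equal(nodeBetweenness(chain), c(A = 0, B = 1, C = 0))

  # undirected path A-B-C: ordered pairs (A,C) and (C,A)
  upath <- relationGraph(c("A", "B", "C"),
    data.frame(from = c("A", "B"), to = c("B", "C"),
               type = "c", directed = FALSE))
  expect_equal(nodeBetweenness(upath), c(A = 0, B = 2, C = 0))

  # undirected 4-cycle: two tied shortest paths between opposite corners,
  # each intermediate gets 1/2 per ordered opposite pair
  cyc <- relationGraph(c("A", "B", "C", "D"),
    data.frame(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "A"),
               type = "c", directed = FALSE))
  expect_equal(nodeBetweenness(cyc), c(A = 1, B = 1, C = 1, D = 1))

  # undirected star with k leaves: centre has k(k-1)
  for (k in c(3, 5, 8)) {
    leaves <- sprintf("L%d", seq_len(k))
    star <- relationGraph(c("hub", leaves),
      data.frame(from = "hub", to = leaves, type = "b", directed = FALSE))
    bt <- nodeBetweenness(star)
    expect_equal(unname(bt["hub"]), k * (k - 1))
    expect_equal(unname(bt[leaves]), rep(0, k))
  }
})

test_that("betweenness agrees with igraph on random mixed graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    g <- randomMixedGraph(seed + 100)
    arcs <- adjacencyArcs(g)
    ids <- graphNodes(g)$id
    ig <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                        vertices = ids)
    expect_equal(nodeBetweenness(g),
                 igraph::betweenness(ig, directed = TRUE)[ids],
                 tolerance = 1e-10)
  }
})

test_that("betweenness is zero for isolated and degree-1 nodes", {
  g <- relationGraph(c("A", "B", "C", "lonely"),
    data.frame(from = c("A", "B"), to = c("B", "C"),
               type = "c", directed = FALSE))
  bt <- nodeBetweenness(g)
  deg <- nodeDegrees(g)
  expect_equal(unname(bt[deg$degree <= 2]), rep(0, 3))  # A, C, lonely
})

test_that("core filtering keeps non-isolated nodes and orders tables", {
  g <- relationGraph(c("A", "B", "C", "D"),
    data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
               type = "link", directed = TRUE))
  tab <- centralityTable(g)
  core <- coreFilter(tab, minDegree = 1)
  expect_setequal(core$id, c("A", "B", "C"))
  expect_false(is.unsorted(rev(core$degree)))      # decreasing degree
  expect_identical(core$rank, seq_len(nrow(core)))

  # every edge endpoint survives min_degree 1
  ends <- unique(c(graphEdges(g)$from, graphEdges(g)$to))
  expect_true(all(ends %in% core$id))

  # all-isolated graph: empty core
  iso <- relationGraph(c("X", "Y"))
  expect_identical(nrow(coreFilter(centralityTable(iso))), 0L)
})

test_that("hub ranking orders by betweenness with degree tie-breaks", {
  g <- relationGraph(c("A", "B", "C", "D", "E"),
    data.frame(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "E"),
               type = "a", directed = TRUE))   # path: B, C, D mediate
  tab <- centralityTable(g)
  hubs <- rankHubs(tab, topK = 2)
  expect_identical(nrow(hubs), 2L)
  expect_identical(hubs$id[1], "C")            # middle of the path
  expect_identical(hubs$rank, 1:2)
  expect_identical(nrow(rankHubs(tab, topK = 50)), 5L)  # whole list
  expect_error(rankHubs(tab, topK = 0), "positive")
})

test_that("edge lists round-trip through write and read", {
  g <- simulateRelationGraph(10, "gene", seed = 3)$graph
  f <- tempfile(fileext = ".tsv")
  writeEdgeList(g, f)
  back <- readEdgeList(f)
  ed <- graphEdges(g)
  expect_identical(back$from, ed$from)
  expect_identical(back$to, ed$to)
  expect_identical(back$type, ed$type)
  expect_identical(back$directed, ed$directed)

  writeLines(c("source\ttarget\ttype", "a\tb\tc"), f)
  expect_error(readEdgeList(f), "source, target")
  writeLines(c("source\ttarget\ttype\tdirected", "a\tb\tweird\t1"), f)
  expect_error(readEdgeList(f), "unknown edge type")
})

test_that("pathway features aggregate member DEG directions", {
  degTab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                       regulation = c("down", "down", "up", "down"))
  expect_identical(
    pathwayFeature(c("g1|g2", "g3", "g1|g3", "g1|g2|g3", "zz"), degTab),
    c("Down", "Up", "Down|up", "Down|up", ""))
})
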