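test_that("d statistic matches the pooled-standard-error formula", {
  vals <- rbind(gA = c(1, 1, 1, 2, 2, 2),
                gB = c(3, 4, 5, 3, 4, 5))
  colnames(vals) <- sprintf("s%d", 1:6)
  ee <- makeExpr(vals, nCtrl = 3)

  st <- samStatistics(ee, s0 = 0.5)
  expect_equal(unname(st["gA", "r"]), 1)
  expect_equal(unname(st["gA", "s"]), 0)
  expect_equal(unname(st["gA", "d"]), 2)      # r/(s + s0) = 1/0.5
  expect_equal(unname(st["gB", "d"]), 0)      # identical group means

  # with s = 0, doubling s0 halves d
  st2 <- samStatistics(ee, s0 = 1)
  expect_equal(unname(st2["gA", "d"]), 1)

  expect_error(samStatistics(ee, s0 = 0), "positive s0")

  # longhand recomputation on random data
  m <- randomMatrix(40, 8, seed = 5)
  st3 <- samStatistics(makeExpr(m, 4), s0 = 0.2)
  dOracle <- vapply(seq_len(40), function(i) oracleD(m[i, ], 1:4, 0.2),
                    numeric(1))
  expect_equal(unname(st3$d), dOracle, tolerance = 1e-12)
})

test_that("s0 estimation is bounded and honours its strategies", {
  expect_equal(estimateS0(rep(3, 50), rnorm(50)), 3)
  expect_equal(estimateS0(1:100, rnorm(100), "percentile"), 50.5)
  set.seed(2)
  s <- rexp(500); r <- rnorm(500, sd = s + 0.1)
  s0 <- estimateS0(s, r, "cv_minimisation")
  expect_gte(s0, min(s))
  expect_lte(s0, max(s))
})

test_that("the permutation null enumerates small designs completely", {
  m <- randomMatrix(10, 4, seed = 3)
  ee <- makeExpr(m, 2)
  null <- permutationNull(ee, s0 = 0.1)
  expect_identical(ncol(null$assignments), 6L)  # choose(4, 2)
  expect_true(null$enumerated)

  # the identity assignment's null d equals the observed d
  idCol <- which(apply(null$assignments, 2, identical, c(1L, 2L)))
  dObs <- samStatistics(ee, s0 = 0.1)$d
  expect_identical(unname(null$d[, idCol]), unname(dObs))

  # balanced enumeration: the pooled null is symmetric about 0
  pool <- as.numeric(null$d)
  expect_equal(sort(pool), sort(-pool))
})

test_that("sampled nulls are seeded, distinct and reproducible", {
  m <- randomMatrix(20, 10, seed = 8)
  ee <- makeExpr(m, 5)  # choose(10,5) = 252 > 100
  n1 <- permutationNull(ee, s0 = 0.1, nPermutations = 100, seed = 9)
  n2 <- permutationNull(ee, s0 = 0.1, nPermutations = 100, seed = 9)
  expect_false(n1$enumerated)
  expect_identical(n1$assignments, n2$assignments)
  keys <- apply(n1$assignments, 2, paste, collapse = ",")
  expect_identical(anyDuplicated(keys), 0L)
  expect_identical(ncol(n1$assignments), 100L)
})

test_that("pooled permutation p follows the add-one convention", {
  nullD <- matrix(c(-1, 0.5, 0.2, -0.3, 0.9, 0.1), 2, 3)
  expect_equal(permutationP(5, nullD), 1 / 7)      # beyond every null value
  expect_equal(permutationP(0, nullD), 1)          # every |null| >= 0
  expect_identical(permutationP(c(0.4, 5), nullD),
                   permutationP(c(0.4, 5), nullD)) # frozen pool, same answer
  expect_equal(permutationP(0.4, nullD), (1 + 3) / 7)
})

test_that("q-values match a brute-force min-over-thresholds recomputation", {
  m <- randomMatrix(50, 6, seed = 21)
  m[1:5, 4:6] <- m[1:5, 4:6] + 2   # a handful of strong genes
  ee <- makeExpr(m, 3)
  st <- samStatistics(ee, s0 = 0.2)
  null <- permutationNull(ee, s0 = 0.2)
  qv <- samQValues(st$d, null$d)
  expect_equal(qv$q, unname(oracleQ(st$d, null$d)), tolerance = 1e-12)

  # q non-increasing in |d|
  o <- order(-abs(st$d))
  expect_false(is.unsorted(qv$q[o]))
  expect_true(all(qv$q >= 0 & qv$q <= 1))
})

test_that("a gene far beyond the null gets q = 0, null-like data get large q", {
  dNull <- matrix(rnorm(200 * 20, sd = 0.5), 200, 20)
  dObs <- c(50, rnorm(199, sd = 0.5))
  qv <- samQValues(dObs, dNull)
  expect_equal(qv$q[1], 0)

  set.seed(4)
  dPure <- rnorm(200, sd = 0.5)       # observed looks like one more draw
  qvNull <- samQValues(dPure, dNull)
  expect_gt(mean(qvNull$q), 0.5)
})

test_that("DEG calling gates on both q and fold change and ranks by p", {
  fakeFit <- function(q, fc, p, d) {
    n <- length(q)
    res <- S4Vectors::DataFrame(
      gene = sprintf("g%02d", seq_len(n)), r = d * 0.1, s = rep(0, n),
      d = d, fold_change = fc, p = p, q = q,
      regulation = ifelse(q < 0.05 & fc > 1.5, "up",
                          ifelse(q < 0.05 & fc < -1.5, "down", "none")),
      rank = seq_len(n))
    methods::new("SamFit", results = res,
                 s0 = 0.1, piZero = 1, nAssignments = 10L, enumerated = TRUE,
                 nullPoolSize = 100, seed = 1L, qThreshold = 0.05,
                 fcThreshold = 1.5)
  }
  fit <- fakeFit(q = c(0.04, 0.04, 0.2, 0.01),
                 fc = c(1.4, -2.5, 3, 2),
                 p = c(0.03, 0.02, 0.001, 0.01),
                 d = c(2, -2.5, 1, 3))
  degs <- callDEGs(fit)
  expect_identical(degs$table$gene, c("g04", "g02"))  # increasing p
  expect_identical(degs$table$rank, 1:2)
  expect_identical(degs$down$gene, "g02")
  expect_identical(degs$up$gene, "g04")               # q=.04, fc=1.4 not called
})

test_that("label swap negates r and d but preserves |d|, p and q", {
  m <- randomMatrix(80, 8, seed = 13)
  m[1:8, 5:8] <- m[1:8, 5:8] + 1.2
  ee <- makeExpr(m, 4)
  fwd <- samFit(ee, s0Strategy = "fixed", s0 = 0.2)
  rev <- samFit(ee, design = rep(c("experimental", "control"), each = 4),
                s0Strategy = "fixed", s0 = 0.2)
  rf <- samResults(fwd); rr <- samResults(rev)
  expect_equal(rr$r, -rf$r)
  expect_equal(rr$d, -rf$d)
  expect_equal(rr$p, rf$p)
  expect_equal(rr$q, rf$q)
  big <- abs(rf$fold_change) > 1
  expect_equal(rr$fold_change[big], -rf$fold_change[big])
  expect_equal(rr$fold_change[!big], rf$fold_change[!big])  # 1 maps to 1
})

test_that("samFit results satisfy the d = r/(s+s0) identity and validity", {
  sim <- simulateExpression(simulationSpec(nGenes = 300, seed = 17))
  fit <- samFit(sim$expr)
  res <- samResults(fit)
  expect_true(all(abs(res$d - res$r / (res$s + fit@s0)) <= 1e-12))
  expect_identical(fit@nAssignments, 924L)
  expect_true(methods::validObject(fit))
  expect_setequal(sort(res$rank), seq_len(nrow(res)))
})
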