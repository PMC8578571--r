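test_that("plain and series-matrix dialects parse to the same matrix", {
  vals <- matrix(c(1.5, 2, 3, 4.25, 5, 6), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  plain <- tempfile(fileext = ".tsv")
  writeExpressionTable(vals, plain)
  sm <- tempfile(fileext = ".txt")
  writeLines(c("!Series_title\tsynthetic fixture",
               "!Series_platform_id\tGPL0000",
               "!series_matrix_table_begin",
               readLines(plain),
               "!series_matrix_table_end"), sm)

  e1 <- readExpressionTable(plain)
  e2 <- readExpressionTable(sm, dialect = "series_matrix")
  expect_equal(dim(e1), c(3L, 2L))
  expect_identical(exprsValues(e1), exprsValues(e2))
  expect_identical(scaleFlag(e1), "log2")
})

test_that("malformed tables fail loudly, missing rows are dropped", {
  f <- tempfile()
  writeLines(c("id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), f)
  expect_error(readExpressionTable(f), "gA")
  writeLines(c("id\ts1\ts2", "gA\t1\tx2", "gB\t3\t4"), f)
  expect_error(readExpressionTable(f), "non-numeric.*gA.*s2")
  writeLines(c("id\ts1\ts2", "gA\t1\tNA", "gB\t3\t4"), f)
  expect_message(e <- readExpressionTable(f), "1 feature")
  expect_identical(rownames(e), "gB")
})

test_that("quantile normalization maps columns onto the mean distribution", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # already-identical columns are a fixed point
  m2 <- cbind(x = c(5, 1, 3), y = c(1, 3, 5))
  expect_equal(quantileNormalize(m2), m2)

  # identical multiset in every column; rank order preserved
  m3 <- randomMatrix(200, 6, seed = 42)
  qn3 <- quantileNormalize(m3)
  sorted <- apply(qn3, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  for (j in 1:6) expect_identical(order(qn3[, j]), order(m3[, j]))
})

test_that("quantile normalization is idempotent and column-exchange equivariant", {
  m <- randomMatrix(150, 5, seed = 7)
  once <- quantileNormalize(m)
  expect_equal(quantileNormalize(once), once, tolerance = 1e-12)

  perm <- c(3, 1, 5, 2, 4)
  expect_equal(quantileNormalize(m[, perm]), quantileNormalize(m)[, perm])
})

test_that("ties receive the mean reference value over their rank span", {
  m <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
  qn <- quantileNormalize(m)
  ref <- rowMeans(apply(m, 2, sort))  # 1.5, 2.5, 5.5
  expect_equal(unname(qn[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  expect_equal(unname(qn[, 2]), ref)
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
  skip_if_not_installed("limma")
  for (seed in 1:5) {
    m <- randomMatrix(100, 4, seed = seed)
    expect_equal(quantileNormalize(m),
                 limma::normalizeQuantiles(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("log2 conversion and its inverse behave", {
  vals <- matrix(c(8, 0, 2, 14), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  lin <- ExpressionExperiment(vals, scale = "linear")
  expect_error(toLog2(lin), "positive pseudocount")
  lg <- toLog2(lin, pseudocount = 1)
  expect_equal(exprsValues(lg)[1, 1], log2(9))
  expect_equal(exprsValues(lg)[2, 1], 0)
  expect_identical(scaleFlag(lg), "log2")
  back <- 2^exprsValues(lg) - 1
  expect_equal(back, vals, tolerance = 1e-9)

  vals8 <- matrix(8, 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_equal(exprsValues(toLog2(ExpressionExperiment(vals8, scale = "linear")))[1, 1], 3)
})

test_that("signed fold change follows the negated-reciprocal convention", {
  vals <- rbind(flat = rep(4, 6), up1 = c(4, 4, 4, 5, 5, 5),
                dn1 = c(5, 5, 5, 4, 4, 4))
  colnames(vals) <- sprintf("s%d", 1:6)
  ee <- makeExpr(vals, nCtrl = 3)
  fc <- signedFoldChange(ee)
  expect_equal(unname(fc), c(1, 2, -2))

  # swapping group labels maps f -> -f for |f| > 1 and fixes 1
  swapped <- rep(c("experimental", "control"), each = 3)
  fcSwap <- signedFoldChange(ee, design = swapped)
  expect_equal(unname(fcSwap), c(1, -2, 2))
})

test_that("design handling validates groups", {
  vals <- randomMatrix(5, 6, seed = 1)
  ee <- ExpressionExperiment(vals)
  expect_null(sampleGroups(ee))
  expect_error(signedFoldChange(ee), "design")
  sampleGroups(ee) <- rep(c("control", "experimental"), each = 3)
  expect_identical(levels(sampleGroups(ee)), c("control", "experimental"))
  expect_error(ExpressionExperiment(vals, groups = rep("control", 6)),
               "non-empty")
})
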