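## Significance Analysis of Microarrays: d statistic, permutation null,
## pooled p-values, discretised-rejection-region q-values, DEG calling.

# core per-gene statistics for an arbitrary control index set
# returns list(r, s): r = mean(expt) - mean(ctrl), s = pooled standard error
.samRS <- function(m, ctrlIdx) {
  n <- ncol(m)
  exptIdx <- setdiff(seq_len(n), ctrlIdx)
  n1 <- length(ctrlIdx); n2 <- length(exptIdx)
  m1 <- rowMeans(m[, ctrlIdx, drop = FALSE])
  m2 <- rowMeans(m[, exptIdx, drop = FALSE])
  ss <- rowSums((m[, ctrlIdx, drop = FALSE] - m1)^2) +
    rowSums((m[, exptIdx, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(r = m2 - m1, s = s)
}

#' Per-gene SAM statistics
#'
#' For each gene computes `r` (difference of group means, experimental minus
#' control, log2 units), `s` (pooled standard error
#' `sqrt((1/n1 + 1/n2) * SSwithin / (n1 + n2 - 2))`) and the regularised
#' statistic `d = r / (s + s0)`.
#'
#' @param x an [ExpressionExperiment-class] on the log2 scale.
#' @param design optional design override: factor/character of
#'   `control`/`experimental` per sample.
#' @param s0 the fudge factor added to `s`.
#' @return a `DataFrame` with columns `gene`, `r`, `s`, `d`.
#' @export
samStatistics <- function(x, design = NULL, s0 = 0) {
  stopifnot(methods::is(x, "ExpressionExperiment"))
  if (scaleFlag(x) != "log2") stop("SAM requires log2-scale values")
  g <- .designOf(x, design)
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  m <- exprsValues(x)
  rs <- .samRS(m, which(g == "control"))
  if (s0 == 0 && any(rs$s == 0))
    stop("gene with zero variance in both groups and s0 = 0: d is ",
         "undefined; supply a positive s0 (or use the default estimator)")
  out <- S4Vectors::DataFrame(gene = rownames(m), r = rs$r, s = rs$s,
                              d = rs$r / (rs$s + s0))
  rownames(out) <- out$gene
  out
}

#' Estimate the SAM fudge factor s0
#'
#' `cv_minimisation` (the canonical Tusher-style choice) evaluates the
#' percentiles 0, 5, ..., 100 of the per-gene standard errors `s` as
#' candidate values and picks the one minimising the coefficient of
#' variation of the d-score spread (median absolute deviation) across
#' s-quantile bins, making the d statistic's scale independent of
#' expression level.  `percentile` simply returns the stated percentile of
#' `s` (default the median).
#'
#' @param s per-gene pooled standard errors.
#' @param r per-gene mean differences (the d numerators).
#' @param strategy `"cv_minimisation"` or `"percentile"`.
#' @param percentile percentile of `s` for the `percentile` strategy.
#' @param nBins number of s-quantile bins for the CV criterion.
#' @return a single non-negative s0 value, always within `[min(s), max(s)]`.
#' @export
estimateS0 <- function(s, r, strategy = c("cv_minimisation", "percentile"),
                       percentile = 50, nBins = 100L) {
  strategy <- match.arg(strategy)
  stopifnot(length(s) == length(r), all(s >= 0))
  if (length(unique(s)) == 1L) return(s[1L])
  if (strategy == "percentile")
    return(unname(quantile(s, percentile / 100)))
  candidates <- unique(unname(quantile(s, seq(0, 1, by = 0.05))))
  breaks <- unique(quantile(s, seq(0, 1, length.out = nBins + 1L)))
  bins <- cut(s, breaks, include.lowest = TRUE)
  cv <- vapply(candidates, function(a) {
    d <- r / (s + a)
    spread <- tapply(d, bins, mad)
    spread <- spread[!is.na(spread)]
    mu <- mean(spread)
    if (mu == 0) Inf else sd(spread) / mu
  }, numeric(1))
  candidates[which.min(cv)]
}

# all (or a seeded sample of) control index sets of size n1 out of n
.assignments <- function(n, n1, nPermutations, seed) {
  total <- choose(n, n1)
  if (total <= nPermutations) {
    list(idx = combn(n, n1), enumerated = TRUE)
  } else {
    idx <- .withSeed(seed, {
      seen <- new.env(hash = TRUE)
      out <- matrix(0L, n1, 0L)
      while (ncol(out) < nPermutations) {
        draw <- sort(sample.int(n, n1))
        key <- paste(draw, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out <- cbind(out, draw)
        }
      }
      out
    })
    list(idx = unname(idx), enumerated = FALSE)
  }
}

#' SAM permutation null
#'
#' Relabels samples into pseudo-groups of the original sizes and recomputes
#' every d score with the s0 fixed from the observed data.  When the number
#' of distinct label assignments is at most `nPermutations` (for the 6 vs 6
#' design, `choose(12, 6) = 924 <= 1000`) all assignments are enumerated
#' exactly once, making the null fully deterministic; otherwise assignments
#' are sampled without replacement under `seed`.  Complementary assignments
#' are both kept: they give distinct signed d whose magnitudes pair up, so
#' the pooled null is symmetric about 0 for balanced designs.
#'
#' @inheritParams samStatistics
#' @param nPermutations maximum number of relabellings (default 1000).
#' @param seed RNG seed, used only when sampling is needed.
#' @param chunkSize relabellings processed per matrix product.
#' @return a list with `d` (genes x assignments null d matrix),
#'   `assignments` (control index sets, one column each), and `enumerated`.
#' @export
permutationNull <- function(x, design = NULL, s0, nPermutations = 1000L,
                            seed = 1L, chunkSize = 256L) {
  stopifnot(methods::is(x, "ExpressionExperiment"))
  g <- .designOf(x, design)
  m <- exprsValues(x)
  n <- ncol(m); n1 <- sum(g == "control"); n2 <- n - n1
  asg <- .assignments(n, n1, as.integer(nPermutations), seed)
  idx <- asg$idx
  B <- ncol(idx)
  m2mat <- m * m
  tS <- rowSums(m); tQ <- rowSums(m2mat)
  dNull <- matrix(0, nrow(m), B)
  fac <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  for (lo in seq(1L, B, by = chunkSize)) {
    hi <- min(lo + chunkSize - 1L, B)
    block <- idx[, lo:hi, drop = FALSE]
    ind <- matrix(0, n, ncol(block))
    ind[cbind(as.vector(block), rep(seq_len(ncol(block)), each = n1))] <- 1
    S1 <- m %*% ind
    Q1 <- m2mat %*% ind
    ss <- pmax(Q1 - S1^2 / n1, 0) + pmax((tQ - Q1) - (tS - S1)^2 / n2, 0)
    r <- (tS - S1) / n2 - S1 / n1
    dNull[, lo:hi] <- r / (sqrt(fac * ss) + s0)
  }
  # the observed labelling (and, for balanced designs, its complement)
  # reappears among the relabellings; recompute those columns through the
  # same code path as the observed statistics so the pooled null contains
  # the observed d (and its exact negation) bitwise, keeping exceedance
  # counts at these self-ties exact
  ctrlIdx <- sort(which(g == "control"))
  for (b in seq_len(B)) {
    a <- idx[, b]
    if (identical(a, ctrlIdx) || identical(a, sort(setdiff(seq_len(n), ctrlIdx)))) {
      rs <- .samRS(m, a)
      dNull[, b] <- rs$r / (rs$s + s0)
    }
  }
  rownames(dNull) <- rownames(m)
  list(d = dNull, assignments = idx, enumerated = asg$enumerated)
}

#' Pooled two-sided permutation p-values
#'
#' The null d values are pooled across genes and relabellings (the SAM
#' convention: per-gene nulls are far too small on 12 arrays) and each
#' gene's two-sided p is the add-one exceedance fraction
#' `p = (1 + #\{|null| >= |d|\}) / (1 + N_null)`, which is never zero.
#'
#' @param observedD numeric vector of observed d scores.
#' @param nullD numeric matrix or vector of null d scores.
#' @return numeric vector of p-values in (0, 1].
#' @export
permutationP <- function(observedD, nullD) {
  pool <- sort(abs(as.numeric(nullD)))
  N <- length(pool)
  if (!N) stop("empty null pool")
  # exceed = #{pool >= |d|} = N - #{pool < |d|}
  exceed <- N - findInterval(abs(observedD), pool, left.open = TRUE)
  (1 + exceed) / (1 + N)
}

#' SAM q-values from discretised rejection regions
#'
#' For every candidate threshold Delta taken at the observed |d| values:
#' observed positives `O = #\{|d| >= Delta\}`, expected false positives
#' `F = median over relabellings of #\{|d_null| >= Delta\}`, and
#' `FDR(Delta) = pi0 * F / max(O, 1)` clipped to \[0, 1\].  A gene's q is the
#' minimum FDR over all thresholds at or below its |d|, so q is
#' non-increasing as |d| grows.  `pi0` is estimated as the ratio of
#' observed to per-relabelling null counts of |d| at or below the null
#' median, capped at 1.
#'
#' @param observedD numeric vector of observed d scores.
#' @param nullD genes x relabellings null d matrix from [permutationNull()].
#' @return list with `q` (per-gene q-values, input order) and `piZero`.
#' @export
samQValues <- function(observedD, nullD) {
  nullD <- as.matrix(nullD)
  B <- ncol(nullD)
  absObs <- abs(observedD)
  absNullPool <- sort(abs(as.numeric(nullD)))
  # pi0: observed vs per-relabelling null mass below the null median of |d|
  d50 <- median(absNullPool)
  nObsLow <- sum(absObs <= d50)
  nNullLow <- findInterval(d50, absNullPool) / B
  piZero <- min(1, nObsLow / nNullLow)

  ord <- order(absObs)            # ascending thresholds
  thr <- absObs[ord]
  G <- length(thr)
  sortedAbs <- thr
  O <- G - findInterval(thr, sortedAbs, left.open = TRUE)
  counts <- matrix(0, B, G)       # per relabelling: #{|null| >= thr}
  for (b in seq_len(B)) {
    nb <- sort(abs(nullD[, b]))
    counts[b, ] <- length(nb) - findInterval(thr, nb, left.open = TRUE)
  }
  Fexp <- apply(counts, 2L, median)
  fdr <- pmin(1, piZero * Fexp / pmax(O, 1))
  qSorted <- cummin(fdr)          # min over Delta <= |d|
  # tied |d| must share the q of their common threshold value
  qSorted <- stats::ave(qSorted, thr, FUN = min)
  q <- numeric(G)
  q[ord] <- qSorted
  list(q = q, piZero = piZero)
}

#' Fit the SAM differential-expression model
#'
#' Runs the full SAM chain on a log2-scale two-group experiment: s0
#' estimation, observed d scores, the permutation null (enumerated when
#' feasible), pooled two-sided permutation p-values, discretised
#' rejection-region q-values, signed fold changes and regulation calls
#' (`up`/`down`/`none` by `q < qThreshold` and `|fold change| >
#' fcThreshold`).  Genes are ranked by increasing p, then q, then id.
#'
#' @inheritParams samStatistics
#' @param nPermutations maximum relabellings for the null (default 1000).
#' @param s0Strategy `"cv_minimisation"` (default), `"percentile"` or
#'   `"fixed"`.
#' @param s0 fixed s0 value (required when `s0Strategy = "fixed"`).
#' @param s0Percentile percentile for the `percentile` strategy.
#' @param seed RNG seed for null sampling (unused when enumerating).
#' @param qThreshold,fcThreshold DEG calling thresholds (defaults 0.05, 1.5).
#' @return a [SamFit-class] object.
#' @examples
#' sim <- simulateExpression(simulationSpec(nGenes = 300, seed = 7))
#' fit <- samFit(sim$expr, nPermutations = 50)
#' fit
#' @export
samFit <- function(x, design = NULL, nPermutations = 1000L,
                   s0Strategy = c("cv_minimisation", "percentile", "fixed"),
                   s0 = NULL, s0Percentile = 50, seed = 1L,
                   qThreshold = 0.05, fcThreshold = 1.5) {
  s0Strategy <- match.arg(s0Strategy)
  stopifnot(qThreshold > 0, fcThreshold > 0, nPermutations >= 1L)
  g <- .designOf(x, design)
  base <- samStatistics(x, design = g, s0 = if (is.null(s0)) 1e-8 else s0)
  s0use <- switch(s0Strategy,
    fixed = {
      if (is.null(s0)) stop("s0Strategy 'fixed' requires 's0'")
      s0
    },
    percentile = estimateS0(base$s, base$r, "percentile",
                            percentile = s0Percentile),
    cv_minimisation = estimateS0(base$s, base$r, "cv_minimisation")
  )
  if (s0use == 0 && any(base$s == 0))
    stop("estimated s0 is 0 while some genes have zero variance; ",
         "supply a positive s0")
  d <- base$r / (base$s + s0use)
  null <- permutationNull(x, design = g, s0 = s0use,
                          nPermutations = nPermutations, seed = seed)
  p <- permutationP(d, null$d)
  qv <- samQValues(d, null$d)
  fc <- signedFoldChange(x, design = g)
  regulation <- rep("none", length(d))
  regulation[qv$q < qThreshold & fc > fcThreshold] <- "up"
  regulation[qv$q < qThreshold & fc < -fcThreshold] <- "down"
  rank <- integer(length(d))
  rank[order(p, qv$q, base$gene)] <- seq_along(d)
  res <- S4Vectors::DataFrame(
    gene = base$gene, r = base$r, s = base$s, d = d,
    fold_change = unname(fc), p = p, q = qv$q,
    regulation = regulation, rank = rank)
  rownames(res) <- base$gene
  methods::new("SamFit",
    results = res, s0 = unname(s0use), piZero = qv$piZero,
    nAssignments = ncol(null$assignments), enumerated = null$enumerated,
    nullPoolSize = as.numeric(ncol(null$assignments)) * nrow(res),
    seed = as.integer(seed), qThreshold = qThreshold,
    fcThreshold = fcThreshold)
}

#' @describeIn SamFit the per-gene results `DataFrame`.
#' @param fit a `SamFit`.
#' @export
samResults <- function(fit) fit@results

setMethod("show", "SamFit", function(object) {
  res <- object@results
  cat("SamFit:", nrow(res), "genes |",
      object@nAssignments,
      if (object@enumerated) "enumerated" else "sampled", "relabellings\n")
  cat(sprintf("  s0 = %.4g | pi0 = %.3f | thresholds: q < %g, |FC| > %g\n",
              object@s0, object@piZero, object@qThreshold,
              object@fcThreshold))
  cat("  called:", sum(res$regulation == "up"), "up,",
      sum(res$regulation == "down"), "down\n")
})

#' Call differentially expressed genes
#'
#' Splits called genes into up- and down-regulated tables, jointly ranked by
#' increasing p, then q, then gene id (the Table-1-style ordering).
#'
#' @param fit a [SamFit-class].
#' @return list with elements `up` and `down` (per-gene `DataFrame`s whose
#'   `rank` column is the joint rank among all called genes) and `table`,
#'   the combined ranked table.
#' @export
callDEGs <- function(fit) {
  res <- samResults(fit)
  called <- res[res$regulation != "none", , drop = FALSE]
  ord <- order(called$p, called$q, called$gene)
  called <- called[ord, , drop = FALSE]
  called$rank <- seq_len(nrow(called))
  list(up = called[called$regulation == "up", , drop = FALSE],
       down = called[called$regulation == "down", , drop = FALSE],
       table = called)
}
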