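#' Construct a gene-set collection
#'
#' Members falling outside the universe are dropped (counted in a message),
#' and sets left empty after the restriction are removed likewise.
#'
#' @param sets named list of character vectors of member gene ids.
#' @param universe character vector of background gene ids.
#' @param descriptions optional named character vector of display names;
#'   defaults to the set ids.
#' @return a [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, universe, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a uniquely named list")
  universe <- unique(as.character(universe))
  restricted <- lapply(sets, function(m) unique(m[m %in% universe]))
  outside <- sum(vapply(sets, function(m)
    sum(!unique(m) %in% universe), integer(1)))
  if (outside > 0)
    message(outside, " member reference(s) outside the universe dropped")
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    message(sum(empty), " empty set(s) dropped")
    restricted <- restricted[!empty]
  }
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(restricted), names(restricted))
  else descriptions <- descriptions[names(restricted)]
  descriptions[is.na(descriptions)] <- names(restricted)[is.na(descriptions)]
  names(descriptions) <- names(restricted)
  methods::new("GeneSetCollection", sets = restricted,
               setDescriptions = descriptions, universe = universe)
}

#' @describeIn GeneSetCollection the member lists.
#' @param x a `GeneSetCollection`.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection the background universe.
#' @export
setUniverse <- function(x) x@universe

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over",
      length(object@universe), "universe genes\n")
  sz <- lengths(object@sets)
  if (length(sz)) cat("  set sizes:", min(sz), "-", max(sz), "\n")
})

#' Read a gene-set collection from a GMT file
#'
#' Format: `set_id <tab> description <tab> member1 <tab> member2 ...`, one
#' set per line.
#'
#' @param path GMT file path.
#' @param universe background gene ids the sets are restricted to.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path, universe) {
  sets <- fgsea::gmtPathways(path)
  desc <- vapply(strsplit(readLines(path), "\t"), function(f)
    if (length(f) >= 2L) f[2L] else f[1L], character(1))
  names(desc) <- vapply(strsplit(readLines(path), "\t"), `[`, character(1), 1L)
  GeneSetCollection(sets, universe, descriptions = desc)
}

#' Write a gene-set collection as GMT
#' @param x a `GeneSetCollection`.
#' @param path output path.
#' @export
writeGmt <- function(x, path) {
  lines <- vapply(names(x@sets), function(id)
    paste(c(id, x@setDescriptions[[id]], x@sets[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin, named wrapper over `stats::p.adjust(method = "BH")`:
#' `fdr_(i) = min over j >= i of m * p_(j) / j`, returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values in input order.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Fisher's exact over-representation of DEGs in gene sets
#'
#' For each set, `p = P[X >= k]` with `X ~ Hypergeometric(N, K, n)` where
#' `N` is the universe size, `K` the set size, `n` the number of DEGs in
#' the universe and `k` the overlap (the one-sided Fisher's exact test for
#' enrichment).  FDR is Benjamini-Hochberg across the collection.  Records
#' are sorted by increasing p (ties by set id) and ranked 1..n.
#'
#' @param degs character vector of differentially expressed gene ids; ids
#'   outside the universe are dropped with a message.
#' @param collection a [GeneSetCollection-class].
#' @return a `DataFrame` with columns `set_id`, `name`, `k`, `K`, `n`, `N`,
#'   `p`, `fdr`, `members_hit` (pipe-delimited), `rank`.
#' @export
fisherEnrich <- function(degs, collection) {
  stopifnot(methods::is(collection, "GeneSetCollection"))
  universe <- setUniverse(collection)
  if (!length(universe)) stop("empty universe")
  degs <- unique(as.character(degs))
  if (!length(degs)) stop("empty DEG list")
  outside <- setdiff(degs, universe)
  if (length(outside)) {
    message(length(outside), " DEG(s) outside the universe dropped")
    degs <- intersect(degs, universe)
    if (!length(degs)) stop("no DEGs left inside the universe")
  }
  N <- length(universe); n <- length(degs)
  sets <- geneSets(collection)
  k <- vapply(sets, function(m) length(intersect(m, degs)), integer(1))
  K <- lengths(sets)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  hits <- vapply(sets, function(m)
    paste(sort(intersect(m, degs)), collapse = "|"), character(1))
  out <- S4Vectors::DataFrame(
    set_id = names(sets), name = unname(collection@setDescriptions),
    k = unname(k), K = unname(K), n = n, N = N,
    p = unname(p), fdr = bhAdjust(unname(p)), members_hit = unname(hits))
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- out$set_id
  out
}

#' Filter enrichment records to the significant sets
#'
#' Keeps records passing the FDR gate (and, optionally, a raw-p gate),
#' preserving the p-ordering and re-ranking 1..n.  Both gates exist because
#' pathway-style analyses are reported under either convention; the FDR
#' gate is the default.
#'
#' @param records output of [fisherEnrich()].
#' @param fdrThreshold keep `fdr < fdrThreshold` (default 0.05); `NULL`
#'   disables the gate.
#' @param pThreshold optional additional `p < pThreshold` gate.
#' @return the filtered, re-ranked `DataFrame`.
#' @export
significantSets <- function(records, fdrThreshold = 0.05, pThreshold = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(fdrThreshold)) keep <- keep & records$fdr < fdrThreshold
  if (!is.null(pThreshold)) keep <- keep & records$p < pThreshold
  out <- records[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Collapse probe-level SAM results to gene symbols
#'
#' When several features map to one gene symbol, keeps the feature with the
#' smallest p (ties by q then feature id), so enrichment sees one record
#' per gene.
#'
#' @param results a SAM results `DataFrame` (see [samResults()]).
#' @param symbols named character vector mapping feature id -> gene symbol;
#'   `NULL` means features already are gene-level ids.
#' @return the collapsed `DataFrame` with a `gene` column of symbols.
#' @export
collapseToGenes <- function(results, symbols = NULL) {
  if (is.null(symbols)) return(results)
  sym <- symbols[results$gene]
  ord <- order(results$p, results$q, results$gene)
  keep <- ord[!duplicated(sym[ord])]
  out <- results[sort(keep), , drop = FALSE]
  out$gene <- unname(symbols[out$gene])
  out
}
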