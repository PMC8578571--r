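#' Construct a two-group expression experiment
#'
#' @param values numeric matrix, features x samples, with row and column
#'   names.  Rows containing missing values are dropped with a message.
#' @param groups optional group assignment: a factor/character vector of
#'   `"control"`/`"experimental"`, either named by sample id or in column
#'   order.
#' @param scale `"log2"` (default) or `"linear"`.
#' @return an [ExpressionExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12, 8), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' ee <- ExpressionExperiment(m, groups = rep(c("control", "experimental"), each = 3))
#' @export
ExpressionExperiment <- function(values, groups = NULL,
                                 scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature and sample names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicated feature id: ", dup[1L])
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicated sample id: ", dup[1L])
  drop <- !stats::complete.cases(values) | rowSums(!is.finite(values)) > 0
  if (any(drop)) {
    message("dropping ", sum(drop), " feature(s) with missing values")
    values <- values[!drop, , drop = FALSE]
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(groups)) cd$group <- .asGroupFactor(groups, colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
  methods::new("ExpressionExperiment", se, scaleFlag = scale)
}

.asGroupFactor <- function(groups, samples) {
  g <- as.character(groups)
  if (!is.null(names(groups))) {
    if (!all(samples %in% names(groups)))
      stop("group assignment missing for sample: ",
           samples[!samples %in% names(groups)][1L])
    g <- g[match(samples, names(groups))]
  } else if (length(g) != length(samples)) {
    stop("group vector length does not match sample count")
  }
  if (!all(g %in% c("control", "experimental")))
    stop("groups must be 'control' or 'experimental'")
  factor(g, levels = c("control", "experimental"))
}

#' @describeIn ExpressionExperiment the expression matrix (assay `exprs`).
#' @param x an `ExpressionExperiment`.
#' @export
exprsValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn ExpressionExperiment the scale flag (`"linear"` or `"log2"`).
#' @export
scaleFlag <- function(x) x@scaleFlag

#' @describeIn ExpressionExperiment the two-group design factor
#'   (levels `control`, `experimental`), or NULL when unset.
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% colnames(cd)) stats::setNames(cd$group, rownames(cd)) else NULL
}

#' @describeIn ExpressionExperiment assign the two-group design.
#' @param value group assignment as in the constructor.
#' @export
`sampleGroups<-` <- function(x, value) {
  cd <- SummarizedExperiment::colData(x)
  cd$group <- .asGroupFactor(value, colnames(x))
  SummarizedExperiment::colData(x) <- cd
  methods::validObject(x)
  x
}

setMethod("show", "ExpressionExperiment", function(object) {
  cat("ExpressionExperiment:", nrow(object), "features x",
      ncol(object), "samples [", object@scaleFlag, "scale ]\n")
  g <- sampleGroups(object)
  if (!is.null(g)) {
    tb <- table(g)
    cat("  design: control n =", tb[["control"]],
        "| experimental n =", tb[["experimental"]], "\n")
  } else cat("  design: unset\n")
})

# resolve a design for an operation: explicit argument wins, else colData
.designOf <- function(x, design = NULL) {
  if (is.null(design)) design <- sampleGroups(x)
  if (is.null(design))
    stop("no group design: set sampleGroups(x) or pass 'design'")
  g <- .asGroupFactor(design, colnames(x))
  if (any(table(g) == 0L)) stop("both groups must be non-empty")
  g
}

#' Read a tab-separated expression table
#'
#' Plain dialect: first column feature id, header row of sample ids.  GEO
#' series-matrix dialect: lines starting with `!` are metadata and are
#' skipped; when `!series_matrix_table_begin`/`_end` markers are present
#' only the enclosed block is parsed.  Quoted identifiers are unquoted.
#' Rows containing missing values are dropped and counted in a message.
#'
#' @param path file path.
#' @param dialect `"plain"` or `"series_matrix"`.
#' @param scale declared scale of the stored values.
#' @param groups optional group assignment (see [ExpressionExperiment()]).
#' @return an [ExpressionExperiment-class].
#' @export
readExpressionTable <- function(path, dialect = c("plain", "series_matrix"),
                                scale = c("log2", "linear"), groups = NULL) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) && length(end) && end[1L] > beg[1L] + 1L)
      lines <- lines[(beg[1L] + 1L):(end[1L] - 1L)]
    else lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression table needs a header and data rows")
  tab <- read.delim(text = lines, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character",
                    quote = "\"")
  ids <- gsub('^"|"$', "", tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated feature id: ", dup[1L])
  sampleIds <- gsub('^"|"$', "", colnames(tab)[-1L])
  dup <- sampleIds[duplicated(sampleIds)]
  if (length(dup)) stop("duplicated sample id: ", dup[1L])
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !(is.na(raw) | raw %in% c("", "NA", "null")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric value at feature '", ids[bad[1L, 1L]],
         "', sample '", sampleIds[bad[1L, 2L]], "'")
  dimnames(num) <- list(ids, sampleIds)
  ExpressionExperiment(num, groups = groups, scale = scale)
}

#' Write an expression table in the plain TSV dialect
#'
#' @param x an `ExpressionExperiment` or numeric matrix.
#' @param path output path.
#' @param idColumn name of the feature-id column.
#' @export
writeExpressionTable <- function(x, path, idColumn = "feature_id") {
  m <- if (methods::is(x, "ExpressionExperiment")) exprsValues(x) else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Each column is mapped onto the across-column mean of sorted values
#' (reference distribution), preserving within-column rank order.  Tied
#' values within a column receive the mean of the reference values over
#' their rank span, the standard microarray convention.  After
#' normalization every tie-free column carries the identical multiset of
#' values, and the operation is idempotent.
#'
#' @param x an [ExpressionExperiment-class] or numeric matrix.
#' @return an object of the same class as `x`.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantileNormalize(m)  # both columns become (2.5, 3.5, 4.5)
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
  if (!all(is.finite(x))) stop("values must be finite")
  if (ncol(x) < 1L) return(x)
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    v <- ref[rank(col, ties.method = "first")]
    out[, j] <- ave(v, col)  # average reference over tied rank spans
  }
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "ExpressionExperiment", function(x) {
  m <- quantileNormalize(exprsValues(x))
  SummarizedExperiment::assay(x, "exprs") <- m
  x
})

#' Convert a linear-scale experiment to log2
#'
#' @param x an `ExpressionExperiment` on the linear scale.
#' @param pseudocount non-negative constant added before the log (default 0).
#' @return the experiment on the log2 scale.
#' @export
toLog2 <- function(x, pseudocount = 0) {
  stopifnot(methods::is(x, "ExpressionExperiment"))
  if (scaleFlag(x) != "linear") stop("input must be on the linear scale")
  m <- exprsValues(x) + pseudocount
  if (any(m <= 0))
    stop("non-positive value after pseudocount; use a positive pseudocount")
  SummarizedExperiment::assay(x, "exprs") <- log2(m)
  x@scaleFlag <- "log2"
  methods::validObject(x)
  x
}

#' Signed linear fold change between the two groups
#'
#' On the log2 scale, let `R = 2^(mean_experimental - mean_control)`.
#' Returns `R` when `R >= 1` and `-1/R` otherwise, so downregulation is
#' negative and a gene with equal group means maps to 1 (Table-style
#' convention: a halving prints as -2, not 0.5).
#'
#' @param x an `ExpressionExperiment` on the log2 scale.
#' @param design optional design override (see [samFit()]).
#' @param genes optional subset of feature ids.
#' @return named numeric vector of signed fold changes.
#' @export
signedFoldChange <- function(x, design = NULL, genes = NULL) {
  stopifnot(methods::is(x, "ExpressionExperiment"))
  if (scaleFlag(x) != "log2") stop("input must be on the log2 scale")
  g <- .designOf(x, design)
  m <- exprsValues(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) stop("unknown feature id: ", missing[1L])
    m <- m[genes, , drop = FALSE]
  }
  diff <- rowMeans(m[, g == "experimental", drop = FALSE]) -
    rowMeans(m[, g == "control", drop = FALSE])
  .signedRatio(diff)
}

# log2 difference -> signed linear ratio
.signedRatio <- function(diffLog2) {
  r <- 2^diffLog2
  ifelse(r >= 1, r, -1 / r)
}
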