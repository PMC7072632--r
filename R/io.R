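## Expression matrix I/O and preprocessing filters.

#' Read an expression matrix from TSV/CSV
#'
#' Loads a delimited text file with a header row and an identifier column,
#' oriented to samples-by-genes. Duplicate gene identifiers, missing cells
#' and non-numeric cells are rejected with messages naming the offenders;
#' no imputation is performed.
#'
#' @param path file path (TSV by default; \code{sep = ","} for CSV).
#' @param orientation \code{"genes_in_rows"} (the common genes-by-samples
#'   layout, transposed on load) or \code{"genes_in_columns"}.
#' @param log2 if TRUE, applies \code{log2(x + 1)} after loading (for
#'   linear-scale inputs; the modeling expects log2-scale values).
#' @param sep field separator (default tab).
#' @return An [ExpressionData-class] (without sample annotations).
#' @export
readExpression <- function(path, orientation = c("genes_in_rows",
                                                 "genes_in_columns"),
                           log2 = FALSE, sep = "\t") {
  orientation <- match.arg(orientation)
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                         check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(d[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop("load error: non-numeric cell(s), first at row '", ids[bad[1, 1]],
         "' column '", colnames(m)[bad[1, 2]], "'")
  }
  rownames(m) <- ids
  if (orientation == "genes_in_rows") m <- t(m)
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    stop("load error: duplicate gene identifier(s): ",
         paste(dup, collapse = ", "))
  }
  if (anyNA(m)) {
    nNA <- sum(is.na(m))
    offGenes <- unique(colnames(m)[col(m)[is.na(m)]])
    stop("load error: ", nNA, " missing value(s) in gene(s): ",
         paste(utils::head(offGenes, 10), collapse = ", "))
  }
  if (log2) m <- log2(m + 1)
  expressionData(m)
}

#' Write an expression matrix as TSV (genes in rows)
#'
#' Inverse of [readExpression()] with the default orientation: genes in
#' rows, samples in columns, full numeric precision so a round trip is
#' value-identical.
#'
#' @param X an [ExpressionData-class] or samples-by-genes matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(X, path) {
  v <- .asExprMatrix(X)
  tv <- t(v)
  out <- cbind(gene = rownames(tv),
               as.data.frame(matrix(sprintf("%.17g", tv), nrow(tv),
                                    dimnames = dimnames(tv)),
                             check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample annotations as TSV
#'
#' @param X an [ExpressionData-class] with sample annotations.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleInfo <- function(X, path) {
  stopifnot(is(X, "ExpressionData"))
  out <- cbind(sample = rownames(X@sampleInfo), X@sampleInfo)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample annotations written by [writeSampleInfo()]
#'
#' @param path TSV path.
#' @return data.frame with rownames set to the sample column.
#' @export
readSampleInfo <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  rownames(d) <- d$sample
  d$sample <- NULL
  d
}

#' Drop genes with low mean expression
#'
#' Removes genes whose mean expression is strictly below the given
#' percentile of all gene means (strictly, so a constant matrix is kept
#' whole). \code{percentile = 0} leaves the data unchanged.
#'
#' @param X an [ExpressionData-class] or samples-by-genes matrix.
#' @param percentile percentile cutoff in [0, 100) (default 15).
#' @return same type as the input, with low-mean genes removed.
#' @export
filterGenesByMeanPercentile <- function(X, percentile = 15) {
  if (percentile < 0 || percentile >= 100)
    stop("percentile must lie in [0, 100)")
  v <- .asExprMatrix(X)
  if (percentile == 0) return(X)
  mu <- colMeans(v)
  cut <- stats::quantile(mu, percentile / 100, type = 7)
  keep <- mu >= cut
  if (is(X, "ExpressionData"))
    expressionData(v[, keep, drop = FALSE], X@sampleInfo)
  else v[, keep, drop = FALSE]
}
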