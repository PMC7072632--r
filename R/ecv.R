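## Edge contribution values: per-sample evaluation of the fitted per-parent
## component functions, their group differences, differential-edge
## extraction, transfer to external cohorts and edge-wise significance.

.ecvColumn <- function(model, k, x) {
  evaluateSpline(model@bases[[k]], model@gamma[[k]], x)
}

#' Compute the samples-by-edges ECv matrix
#'
#' For every edge (parent -> child) of the model set and every sample, the
#' ECv is the child's fitted component function for that parent, evaluated
#' at the sample's parent expression. Column order follows the model set's
#' edge enumeration.
#'
#' Absolute ECv levels carry an arbitrary per-component constant (the
#' additive decomposition is identified only up to constants); every
#' downstream comparison differences these constants out.
#'
#' @param models a [ModelSet-class].
#' @param X an [ExpressionData-class] or samples-by-genes matrix containing
#'   every parent gene of every edge (use [transferEcv()] for partial gene
#'   sets).
#' @return An [EcvMatrix-class].
#' @export
computeEcvMatrix <- function(models, X) {
  stopifnot(is(models, "ModelSet"))
  v <- .asExprMatrix(X)
  e <- models@edges
  missing <- setdiff(unique(e$parent), colnames(v))
  if (length(missing))
    stop("lookup error: parent gene(s) absent from expression data: ",
         paste(missing, collapse = ", "))
  vals <- matrix(0, nrow(v), nrow(e))
  for (i in seq_len(nrow(e))) {
    m <- models@models[[e$child[i]]]
    vals[, i] <- .ecvColumn(m, e$k[i], v[, e$parent[i]])
  }
  rownames(vals) <- rownames(v)
  colnames(vals) <- paste0(e$parent, "->", e$child)
  new("EcvMatrix", values = vals,
      edges = data.frame(parent = e$parent, child = e$child,
                         stringsAsFactors = FALSE),
      provenance = "computeEcvMatrix")
}

.resolveSamples <- function(E, s) {
  if (is.character(s)) {
    idx <- match(s, rownames(E@values))
    if (anyNA(idx)) stop("unknown sample(s): ", paste(s[is.na(idx)],
                                                      collapse = ", "))
    idx
  } else as.integer(s)
}

#' Absolute difference of mean ECv between two sample groups
#'
#' For every edge, the absolute difference between the mean ECv over the
#' samples in \code{S} and the mean over the samples in \code{T}. Either
#' group may contain a single sample.
#'
#' @param E an [EcvMatrix-class].
#' @param S,T sample indices or names; non-empty, disjoint sets within one
#'   comparison.
#' @return named numeric vector (one non-negative value per edge).
#' @export
deltaEcv <- function(E, S, T) {
  stopifnot(is(E, "EcvMatrix"))
  si <- .resolveSamples(E, S)
  ti <- .resolveSamples(E, T)
  if (!length(si) || !length(ti))
    stop("empty-group error: S and T must be non-empty")
  abs(colMeans(E@values[si, , drop = FALSE]) -
        colMeans(E@values[ti, , drop = FALSE]))
}

#' Per-group delta-ECv table
#'
#' Computes [deltaEcv()] for each named group pairing (for instance one
#' pairing per cell line) and returns an edges-by-groups table.
#'
#' @param E an [EcvMatrix-class].
#' @param groups named list; each element is a list with components \code{S}
#'   and \code{T} (sample indices or names).
#' @return data.frame with columns \code{parent}, \code{child} and one
#'   delta-ECv column per group.
#' @export
deltaEcvTable <- function(E, groups) {
  stopifnot(is(E, "EcvMatrix"), length(groups) >= 1L,
            !is.null(names(groups)))
  out <- data.frame(parent = E@edges$parent, child = E@edges$child,
                    stringsAsFactors = FALSE)
  for (g in names(groups))
    out[[g]] <- unname(deltaEcv(E, groups[[g]]$S, groups[[g]]$T))
  out
}

#' Extract condition-differential edges from a delta-ECv table
#'
#' Keeps edges whose delta-ECv exceeds the threshold in every group
#' (\code{mode = "all"}, the default extraction rule) or in at least one
#' group (\code{mode = "any"}). The returned table carries the per-group
#' delta-ECv annotations.
#'
#' @param table a data.frame as returned by [deltaEcvTable()]: columns
#'   \code{parent}, \code{child}, then one numeric column per group.
#' @param threshold positive delta-ECv threshold (default 1.0, a two-fold
#'   change on log2-scale expression).
#' @param mode \code{"all"} or \code{"any"}.
#' @return data.frame subset of \code{table} (possibly zero rows).
#' @export
extractDifferentialEdges <- function(table, threshold = 1.0,
                                     mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive")
  groupCols <- setdiff(names(table), c("parent", "child"))
  if (!length(groupCols)) stop("no group columns in delta-ECv table")
  hits <- as.matrix(table[, groupCols, drop = FALSE]) > threshold
  keep <- if (mode == "all") rowSums(hits) == length(groupCols)
  else rowSums(hits) > 0
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transfer fitted edge models to a new expression cohort
#'
#' Evaluates the original training models, unchanged, on a new cohort's
#' expression (same log2-scale convention as training). An edge is
#' computable when both its parent and child genes are present in the new
#' data; parent values outside the training range are clamped to the range
#' boundary. The report accounts for shared genes, missing genes and
#' dropped edges.
#'
#' @param models a [ModelSet-class] trained on the original cohort.
#' @param newX an [ExpressionData-class] or samples-by-genes matrix for the
#'   new cohort.
#' @param edges optional data.frame with columns \code{parent}, \code{child}
#'   restricting transfer to an edge subset (e.g. the extracted differential
#'   edges); default all model-set edges.
#' @param rescale if TRUE, z-scale each shared gene in \code{newX} to the
#'   training mean/sd before evaluation; defaults to FALSE (values are
#'   plugged into the trained models unchanged).
#' @return list with components \code{ecv} (an [EcvMatrix-class] over the
#'   computable edges) and \code{report} (list: \code{nModelGenes},
#'   \code{sharedGenes}, \code{missingGenes}, \code{nRequestedEdges},
#'   \code{computableEdges}, \code{droppedEdges}).
#' @export
transferEcv <- function(models, newX, edges = NULL, rescale = FALSE) {
  stopifnot(is(models, "ModelSet"))
  v <- .asExprMatrix(newX)
  e <- if (is.null(edges)) models@edges else {
    key <- paste(edges$parent, edges$child, sep = "\r")
    mkey <- paste(models@edges$parent, models@edges$child, sep = "\r")
    idx <- match(key, mkey)
    if (anyNA(idx))
      stop("requested edge(s) not in the model set: ",
           paste(key[is.na(idx)], collapse = ", "))
    models@edges[idx, , drop = FALSE]
  }
  edgeGenes <- unique(c(e$parent, e$child))
  shared <- intersect(edgeGenes, colnames(v))
  missing <- setdiff(edgeGenes, colnames(v))
  ok <- e$parent %in% shared & e$child %in% shared
  dropped <- e[!ok, c("parent", "child"), drop = FALSE]
  rownames(dropped) <- NULL
  e <- e[ok, , drop = FALSE]
  if (!nrow(e))
    stop("empty-transfer error: no edge has both genes in the new data")
  if (rescale) {
    ts <- models@trainStats
    for (g in intersect(shared, ts$gene)) {
      i <- match(g, ts$gene)
      s <- stats::sd(v[, g])
      if (is.finite(s) && s > 0 && is.finite(ts$sd[i]) && ts$sd[i] > 0)
        v[, g] <- (v[, g] - mean(v[, g])) / s * ts$sd[i] + ts$mean[i]
    }
  }
  vals <- matrix(0, nrow(v), nrow(e))
  for (i in seq_len(nrow(e))) {
    m <- models@models[[e$child[i]]]
    vals[, i] <- .ecvColumn(m, e$k[i], v[, e$parent[i]])
  }
  rownames(vals) <- rownames(v)
  colnames(vals) <- paste0(e$parent, "->", e$child)
  ecv <- new("EcvMatrix", values = vals,
             edges = data.frame(parent = e$parent, child = e$child,
                                stringsAsFactors = FALSE),
             provenance = "transferEcv")
  report <- list(
    nModelGenes = length(edgeGenes),
    sharedGenes = sort(shared),
    missingGenes = sort(missing),
    nRequestedEdges = length(ok),
    computableEdges = nrow(e),
    droppedEdges = dropped
  )
  list(ecv = ecv, report = report)
}

#' Edge-wise two-sample tests on ECv values
#'
#' Welch (unequal-variance) two-sample t-test per edge between the sample
#' groups \code{S} and \code{T}, with Benjamini-Hochberg adjustment across
#' the tested edges. When both groups have zero variance the test is
#' degenerate: p is 1 for equal means and 0 otherwise.
#'
#' @param E an [EcvMatrix-class].
#' @param S,T sample indices or names, each with at least two samples.
#' @return data.frame with columns \code{parent}, \code{child}, \code{t},
#'   \code{p}, \code{q}.
#' @export
ecvEdgeTests <- function(E, S, T) {
  stopifnot(is(E, "EcvMatrix"))
  si <- .resolveSamples(E, S)
  ti <- .resolveSamples(E, T)
  if (length(si) < 2L || length(ti) < 2L)
    stop("insufficient replicates: both groups need at least 2 samples")
  m <- ncol(E@values)
  tt <- pp <- numeric(m)
  for (v in seq_len(m)) {
    x <- E@values[si, v]
    y <- E@values[ti, v]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      tt[v] <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
      pp[v] <- if (mean(x) == mean(y)) 1 else 0
    } else {
      res <- stats::t.test(x, y, var.equal = FALSE)
      tt[v] <- unname(res$statistic)
      pp[v] <- res$p.value
    }
  }
  data.frame(parent = E@edges$parent, child = E@edges$child, t = tt, p = pp,
             q = stats::p.adjust(pp, method = "BH"), stringsAsFactors = FALSE)
}

#' Plain Welch-t differential expression helper
#'
#' Per-gene Welch t-test between two sample groups with log2 fold change
#' (difference of group means on the log2 scale) and Benjamini-Hochberg
#' adjustment. Provided for side-by-side comparison of expression-level and
#' edge-level differences; it is not a moderated-variance DEG pipeline.
#'
#' @param X an [ExpressionData-class] or samples-by-genes matrix of
#'   log2-scale expression.
#' @param S,T sample indices or names (>= 2 each).
#' @return data.frame with columns \code{gene}, \code{log2FC}, \code{t},
#'   \code{p}, \code{q}.
#' @export
degTest <- function(X, S, T) {
  v <- .asExprMatrix(X)
  si <- if (is.character(S)) match(S, rownames(v)) else as.integer(S)
  ti <- if (is.character(T)) match(T, rownames(v)) else as.integer(T)
  if (length(si) < 2L || length(ti) < 2L)
    stop("insufficient replicates: both groups need at least 2 samples")
  p <- ncol(v)
  lfc <- tt <- pp <- numeric(p)
  for (j in seq_len(p)) {
    x <- v[si, j]
    y <- v[ti, j]
    lfc[j] <- mean(x) - mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      tt[j] <- 0
      pp[j] <- if (lfc[j] == 0) 1 else 0
    } else {
      res <- stats::t.test(x, y, var.equal = FALSE)
      tt[j] <- unname(res$statistic)
      pp[j] <- res$p.value
    }
  }
  data.frame(gene = colnames(v), log2FC = lfc, t = tt, p = pp,
             q = stats::p.adjust(pp, method = "BH"), stringsAsFactors = FALSE)
}

#' Write an ECv matrix as TSV
#'
#' Samples in rows, edges in columns (edge id \code{"parent->child"}), full
#' numeric precision.
#'
#' @param E an [EcvMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEcvMatrix <- function(E, path) {
  stopifnot(is(E, "EcvMatrix"))
  v <- E@values
  out <- cbind(sample = rownames(v),
               as.data.frame(matrix(sprintf("%.17g", v), nrow(v),
                                    dimnames = dimnames(v)),
                             check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ECv matrix written by [writeEcvMatrix()]
#'
#' @param path TSV path.
#' @return An [EcvMatrix-class].
#' @export
readEcvMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(d[, -1, drop = FALSE])
  rownames(v) <- d$sample
  parts <- strsplit(colnames(v), "->", fixed = TRUE)
  new("EcvMatrix", values = v,
      edges = data.frame(parent = vapply(parts, `[`, character(1), 1L),
                         child = vapply(parts, `[`, character(1), 2L),
                         stringsAsFactors = FALSE),
      provenance = paste0("readEcvMatrix:", path))
}
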