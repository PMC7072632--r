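#' Fit the additive B-spline regression of a child gene on its parents
#'
#' Models the child's expression as a sum of per-parent smooth components
#' plus Gaussian noise. Coefficients minimize the residual sum of squares
#' penalized by a second-order difference penalty per parent (the standard
#' P-spline smoothness prior) plus a small ridge term that pins a unique
#' decomposition; the smoothness weight is chosen from
#' \code{cfg@lambdaGrid} by the local marginal-likelihood score. A child with
#' no parents is fitted as a Gaussian around the sample mean.
#'
#' @param X an [ExpressionData-class] or samples-by-genes matrix.
#' @param child child gene name (a column of \code{X}).
#' @param parents character vector of parent gene names (may be empty).
#' @param cfg a [ScoreConfig-class].
#' @return A [LocalModel-class].
#' @examples
#' x <- seq(0, 1, length.out = 50)
#' X <- cbind(a = x, b = 2 * x)
#' rownames(X) <- paste0("s", 1:50)
#' m <- fitLocalModel(X, "b", "a", scoreConfig(M = 10))
#' componentValue(m, 1, 0.5)
#' @export
fitLocalModel <- function(X, child, parents = character(), cfg = scoreConfig()) {
  v <- .asExprMatrix(X)
  if (length(parents) > cfg@maxParents)
    stop("parent set larger than cfg@maxParents")
  missing <- setdiff(c(child, parents), colnames(v))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  cache <- .scoreCache(v[, unique(c(child, parents)), drop = FALSE], cfg)
  ci <- .geneIndex(cache, child)
  pi <- if (length(parents)) .geneIndex(cache, parents) else integer()
  fit <- .fitRaw(cache, ci, pi)
  new("LocalModel",
      child = child,
      parents = as.character(parents),
      bases = cache$bases[pi],
      gamma = fit$gamma,
      sigma2 = fit$sigma2,
      constant = fit$constant,
      nTrain = cache$n)
}

#' Evaluate one fitted component function of a local model
#'
#' Returns \eqn{m_k(x)}, the fitted smooth transmission of the k-th parent,
#' evaluated at \code{x} (clamped to the parent's training range). This is
#' the kernel of the edge contribution value: the ECv of the edge
#' (k-th parent -> child) in a sample is this component at the sample's
#' parent expression.
#'
#' @param model a [LocalModel-class].
#' @param k parent index, 1-based.
#' @param x numeric vector of parent expression values.
#' @return numeric vector of component values.
#' @export
componentValue <- function(model, k, x) {
  stopifnot(is(model, "LocalModel"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(model@parents))
    stop("index error: component k out of range")
  evaluateSpline(model@bases[[k]], model@gamma[[k]], x)
}

#' Predicted child expression under a fitted local model
#'
#' Sum of the fitted per-parent components (plus the fitted constant for a
#' parentless model) at the supplied parent values.
#'
#' @param model a [LocalModel-class].
#' @param parentValues numeric matrix (or named data.frame) whose columns are
#'   the model's parents in order; ignored for parentless models.
#' @return numeric vector of predictions.
#' @export
predictLocalModel <- function(model, parentValues = NULL) {
  q <- length(model@parents)
  if (q == 0L) {
    nOut <- if (is.null(parentValues)) 1L else NROW(parentValues)
    return(rep(model@constant, nOut))
  }
  pv <- as.matrix(parentValues)
  if (ncol(pv) != q)
    stop("need one column of parent values per parent")
  out <- numeric(nrow(pv))
  for (k in seq_len(q))
    out <- out + componentValue(model, k, pv[, k])
  out
}

#' Penalized marginal-likelihood score of a candidate parent set
#'
#' A Laplace-style closed-form criterion: the Gaussian likelihood with the
#' noise variance profiled out, a block second-difference smoothness prior on
#' the spline coefficients, and the log-determinant complexity term of the
#' penalized normal-equation matrix. The score is maximized over the lambda
#' grid, is deterministic given its inputs, and is higher for better
#' parent sets; structure search maximizes its sum over children.
#'
#' @inheritParams fitLocalModel
#' @return A single numeric score (higher is better).
#' @export
localLogScore <- function(X, child, parents = character(), cfg = scoreConfig()) {
  v <- .asExprMatrix(X)
  missing <- setdiff(c(child, parents), colnames(v))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  cache <- .scoreCache(v[, unique(c(child, parents)), drop = FALSE], cfg)
  ci <- .geneIndex(cache, child)
  pi <- if (length(parents)) .geneIndex(cache, parents) else integer()
  .scoreRaw(cache, ci, pi)$score
}

#' Fit local models for every node of a network
#'
#' Produces the [ModelSet-class] that is the single source of fitted
#' component functions for all ECv computation: one [LocalModel-class] per
#' network gene, with parents taken from the network's edge list (nodes
#' without parents get constant models). The edge enumeration of the
#' returned set (ordered by child, then by parent order within the child)
#' fixes the column order of every ECv matrix computed from it.
#'
#' @param X an [ExpressionData-class] or samples-by-genes matrix containing
#'   every network gene.
#' @param network a [BasalNetwork-class].
#' @param cfg a [ScoreConfig-class].
#' @return A [ModelSet-class].
#' @export
fitAllModels <- function(X, network, cfg = scoreConfig()) {
  stopifnot(is(network, "BasalNetwork"))
  v <- .asExprMatrix(X)
  genes <- network@genes
  missing <- setdiff(genes, colnames(v))
  if (length(missing))
    stop("network genes absent from expression data: ",
         paste(missing, collapse = ", "))
  cache <- .scoreCache(v[, genes, drop = FALSE], cfg)
  parentMap <- split(network@edges$parent, network@edges$child)
  models <- vector("list", length(genes))
  names(models) <- genes
  edgeParent <- character()
  edgeChild <- character()
  edgeK <- integer()
  for (g in genes) {
    pa <- parentMap[[g]]
    if (is.null(pa)) pa <- character()
    ci <- .geneIndex(cache, g)
    pi <- if (length(pa)) .geneIndex(cache, pa) else integer()
    fit <- .fitRaw(cache, ci, pi)
    models[[g]] <- new("LocalModel", child = g, parents = as.character(pa),
                       bases = cache$bases[pi], gamma = fit$gamma,
                       sigma2 = fit$sigma2, constant = fit$constant,
                       nTrain = cache$n)
    if (length(pa)) {
      edgeParent <- c(edgeParent, pa)
      edgeChild <- c(edgeChild, rep(g, length(pa)))
      edgeK <- c(edgeK, seq_along(pa))
    }
  }
  new("ModelSet", models = models, genes = genes,
      edges = data.frame(parent = edgeParent, child = edgeChild, k = edgeK,
                         stringsAsFactors = FALSE),
      trainStats = data.frame(gene = genes,
                              mean = colMeans(v[, genes, drop = FALSE]),
                              sd = apply(v[, genes, drop = FALSE], 2, stats::sd),
                              stringsAsFactors = FALSE, row.names = NULL))
}
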