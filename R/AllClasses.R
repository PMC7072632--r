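#' @import methods
NULL

#' Clamped cubic B-spline basis over an observed range
#'
#' A third-order (cubic) B-spline basis determined by the range of the
#' observations it was built from. The knot vector is clamped: the boundary
#' knots are repeated \code{degree + 1} times so that the first (last) basis
#' function equals one at the lower (upper) end of the support. Evaluation
#' outside the support is defined by clamping the query point to the nearest
#' boundary, which keeps downstream model transfer to out-of-range cohort
#' values bounded.
#'
#' @slot degree integer, polynomial degree (fixed at 3).
#' @slot M integer, number of basis functions.
#' @slot knots numeric, nondecreasing knot vector of length \code{M + degree + 1}.
#' @slot supportLo,supportHi numeric, the observation range the basis spans.
#'
#' @seealso [buildBasis()], [evaluateBasis()], [evaluateSpline()]
#' @export
setClass("SplineBasis",
  representation(
    degree = "integer",
    M = "integer",
    knots = "numeric",
    supportLo = "numeric",
    supportHi = "numeric"
  )
)

setValidity("SplineBasis", function(object) {
  msg <- character()
  if (length(object@M) != 1L || object@M < 4L)
    msg <- c(msg, "M must be a single integer >= 4")
  if (object@degree != 3L)
    msg <- c(msg, "degree must be 3 (cubic basis)")
  if (length(object@knots) != object@M + object@degree + 1L)
    msg <- c(msg, "knot vector must have length M + degree + 1")
  if (is.unsorted(object@knots))
    msg <- c(msg, "knots must be nondecreasing")
  if (!(object@supportLo < object@supportHi))
    msg <- c(msg, "supportLo must be strictly below supportHi")
  if (length(msg)) msg else TRUE
})

#' Configuration for local-model fitting and scoring
#'
#' Bundles the hyperparameters of the additive B-spline regression and its
#' penalized marginal-likelihood score: the basis size \code{M}, the grid of
#' candidate smoothness weights \code{lambdaGrid} (each local model picks the
#' grid value maximizing its score), a small ridge term \code{ridgeEps} that
#' pins a unique coefficient decomposition, and the parent-set size cap used
#' by the structure search.
#'
#' @slot M integer, number of B-spline basis functions per parent (default 20).
#' @slot lambdaGrid numeric, positive candidate smoothness hyperparameters.
#' @slot ridgeEps numeric, small positive ridge regularizer.
#' @slot maxParents integer, maximum parents per child in structure search.
#'
#' @export
setClass("ScoreConfig",
  representation(
    M = "integer",
    lambdaGrid = "numeric",
    ridgeEps = "numeric",
    maxParents = "integer"
  ),
  prototype(
    M = 20L,
    lambdaGrid = c(0.1, 1, 10, 100),
    ridgeEps = 1e-8,
    maxParents = 3L
  )
)

setValidity("ScoreConfig", function(object) {
  msg <- character()
  if (object@M < 4L) msg <- c(msg, "M must be >= 4")
  if (length(object@lambdaGrid) == 0L || any(object@lambdaGrid <= 0))
    msg <- c(msg, "lambdaGrid must be non-empty and strictly positive")
  if (length(object@ridgeEps) != 1L || object@ridgeEps <= 0)
    msg <- c(msg, "ridgeEps must be a single positive number")
  if (object@maxParents < 0L) msg <- c(msg, "maxParents must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ScoreConfig-class
#' @param M number of B-spline basis functions per parent.
#' @param lambdaGrid positive candidate smoothness hyperparameters.
#' @param ridgeEps small positive ridge regularizer.
#' @param maxParents maximum parents per child.
#' @return A \code{ScoreConfig} object.
#' @examples
#' scoreConfig(M = 10)
#' @export
scoreConfig <- function(M = 20L, lambdaGrid = c(0.1, 1, 10, 100),
                        ridgeEps = 1e-8, maxParents = 3L) {
  new("ScoreConfig", M = as.integer(M), lambdaGrid = as.numeric(lambdaGrid),
      ridgeEps = as.numeric(ridgeEps), maxParents = as.integer(maxParents))
}

#' Fitted additive B-spline regression of a child gene on its parents
#'
#' The child's expression is modeled as a sum of per-parent smooth components
#' plus Gaussian noise; each component is a B-spline curve with its own basis
#' (built from the training range of that parent) and coefficient vector.
#' A parentless child is modeled as a Gaussian around the sample mean, stored
#' in \code{constant}. The per-parent component evaluated at a sample's parent
#' expression is that edge's contribution value (ECv).
#'
#' Additive components are identified only up to additive constants; the ridge
#' term in the fit pins one reproducible decomposition. Absolute component
#' levels therefore carry an arbitrary offset which cancels in all ECv
#' differences.
#'
#' @slot child character, child gene identifier.
#' @slot parents character, ordered parent gene identifiers (may be empty).
#' @slot bases list of [SplineBasis-class], one per parent.
#' @slot gamma list of numeric coefficient vectors (length M), one per parent.
#' @slot sigma2 numeric, residual variance (residual sum of squares / n).
#' @slot constant numeric, fitted constant (sample mean) for parentless models,
#'   0 otherwise.
#' @slot nTrain integer, number of training samples.
#'
#' @export
setClass("LocalModel",
  representation(
    child = "character",
    parents = "character",
    bases = "list",
    gamma = "list",
    sigma2 = "numeric",
    constant = "numeric",
    nTrain = "integer"
  )
)

setValidity("LocalModel", function(object) {
  q <- length(object@parents)
  msg <- character()
  if (length(object@bases) != q || length(object@gamma) != q)
    msg <- c(msg, "parents, bases and gamma must have equal length")
  if (length(object@sigma2) != 1L || object@sigma2 < 0)
    msg <- c(msg, "sigma2 must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' A set of fitted local models covering a network
#'
#' One [LocalModel-class] per network node, together with the edge
#' enumeration used to order columns of every ECv matrix computed from the
#' set. This is the single source of the fitted component functions for all
#' ECv operations, and it serializes losslessly to JSON (see
#' [writeModelSet()]).
#'
#' @slot models named list of [LocalModel-class], keyed by child gene.
#' @slot genes character, the gene universe of the network.
#' @slot edges data.frame with columns \code{parent}, \code{child}, \code{k}
#'   (the parent's index within the child's parent list).
#' @slot trainStats data.frame with columns \code{gene}, \code{mean},
#'   \code{sd}: training-cohort location and scale per gene, used by the
#'   optional rescaling in [transferEcv()].
#'
#' @export
setClass("ModelSet",
  representation(
    models = "list",
    genes = "character",
    edges = "data.frame",
    trainStats = "data.frame"
  ),
  prototype(
    trainStats = data.frame(gene = character(), mean = numeric(),
                            sd = numeric(), stringsAsFactors = FALSE)
  )
)

setValidity("ModelSet", function(object) {
  msg <- character()
  if (!all(c("parent", "child", "k") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns parent, child, k")
  if (!all(names(object@models) %in% object@genes))
    msg <- c(msg, "every model child must be in the gene universe")
  if (length(msg)) msg else TRUE
})

#' Edge frequencies from the iterated-subnetwork estimator
#'
#' Result of repeating subnetwork estimation on sampled gene subsets: for
#' every directed edge, the number of estimated subnetworks containing it and
#' the number of sampled subsets containing both endpoints. The frequency is
#' their ratio, so rarely co-sampled pairs are not penalized.
#'
#' @slot genes character, gene universe.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{count}, \code{cosampled}, \code{frequency}.
#' @slot pairs data.frame with columns \code{gene1}, \code{gene2} (unordered,
#'   gene1 < gene2) and \code{cosampled}: how often both genes appeared in
#'   one sampled subset.
#' @slot tIter integer, number of subnetwork estimations performed.
#' @slot subsetSize integer, genes per sampled subset.
#' @slot seed integer, seed the run was keyed by.
#'
#' @export
setClass("EdgeFrequencyNetwork",
  representation(
    genes = "character",
    edges = "data.frame",
    pairs = "data.frame",
    tIter = "integer",
    subsetSize = "integer",
    seed = "integer"
  )
)

setValidity("EdgeFrequencyNetwork", function(object) {
  msg <- character()
  need <- c("parent", "child", "count", "cosampled", "frequency")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, "edges must have columns parent, child, count, cosampled, frequency")
  else {
    f <- object@edges$frequency
    if (length(f) && (any(f < 0) || any(f > 1)))
      msg <- c(msg, "frequencies must lie in [0, 1]")
    if (length(f) && any(f > 0 & object@edges$cosampled == 0))
      msg <- c(msg, "positive frequency requires positive cosample count")
  }
  if (length(msg)) msg else TRUE
})

#' Basal network: the thresholded directed gene network
#'
#' The directed network obtained by keeping edges whose estimated frequency
#' exceeds a cutoff (or returned directly by the exact/greedy searches).
#' The network may contain cycles after frequency thresholding; ECv needs
#' only the per-child regressions, so global acyclicity is not re-imposed.
#'
#' @slot genes character, gene universe.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{frequency}.
#'
#' @export
setClass("BasalNetwork",
  representation(
    genes = "character",
    edges = "data.frame"
  )
)

setValidity("BasalNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("parent", "child") %in% names(e)))
    return("edges must have columns parent and child")
  if (nrow(e)) {
    if (any(e$parent == e$child)) msg <- c(msg, "self-loops are forbidden")
    if (anyDuplicated(paste(e$parent, e$child, sep = "\r")))
      msg <- c(msg, "duplicate edges are forbidden")
    if (!all(c(e$parent, e$child) %in% object@genes))
      msg <- c(msg, "all edge endpoints must be in the gene universe")
  }
  if (length(msg)) msg else TRUE
})

#' Samples-by-edges matrix of edge contribution values
#'
#' Each entry is the fitted component function of an edge evaluated at the
#' corresponding sample's parent expression: the edge's contribution to its
#' child's predicted expression in that sample. Column names are edge
#' identifiers of the form \code{"parent->child"}.
#'
#' @slot values numeric matrix, samples (rows) by edges (columns).
#' @slot edges data.frame with columns \code{parent}, \code{child} matching
#'   the column order of \code{values}.
#' @slot provenance character, free-text note on the model set that produced
#'   the matrix.
#'
#' @export
setClass("EcvMatrix",
  representation(
    values = "matrix",
    edges = "data.frame",
    provenance = "character"
  )
)

setValidity("EcvMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != nrow(object@edges))
    msg <- c(msg, "one edge row per value column required")
  if (nrow(object@values) && any(!is.finite(object@values)))
    msg <- c(msg, "ECv values must be finite")
  if (length(msg)) msg else TRUE
})

#' Differential subnetwork assembled from extracted edges
#'
#' Node set: the endpoints of the differential (extracted) edges. Edge set:
#' the extracted edges plus every basal-network edge whose both endpoints are
#' extracted nodes, i.e. the basal-network induced subgraph on the extracted
#' genes. Each edge is tagged by origin.
#'
#' @slot nodes character, genes of the extracted edges.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{origin} (\code{"delta_extracted"} or \code{"basal_fill"}) plus any
#'   per-group delta-ECv annotation columns carried over from extraction.
#'
#' @export
setClass("Subnetwork",
  representation(
    nodes = "character",
    edges = "data.frame"
  )
)

setValidity("Subnetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("parent", "child", "origin") %in% names(e)))
    return("edges must have columns parent, child, origin")
  if (nrow(e)) {
    if (!all(e$origin %in% c("delta_extracted", "basal_fill")))
      msg <- c(msg, "origin must be delta_extracted or basal_fill")
    if (!all(c(e$parent, e$child) %in% object@nodes))
      msg <- c(msg, "edges may only connect subnetwork nodes")
    if (anyDuplicated(paste(e$parent, e$child, sep = "\r")))
      msg <- c(msg, "duplicate edges are forbidden")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth for the synthetic-data generator
#'
#' A known directed acyclic network with per-edge transmission functions,
#' per-node noise levels, and a designated set of perturbed edges whose
#' upstream regulator is shifted in the treated condition. The experimental
#' design mirrors a multi-cell-line, two-condition replicate layout.
#'
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{family} (linear, sigmoid, sine or quadratic) and numeric
#'   parameters \code{a}, \code{b}, \code{c}.
#' @slot genes character, topologically ordered is not required.
#' @slot sigma named numeric, per-node noise standard deviation.
#' @slot baseline named numeric, per-node baseline (intercept) expression.
#' @slot perturbed data.frame with columns \code{parent}, \code{child}: the
#'   designated condition-responsive edges.
#' @slot shift numeric, magnitude of the treated-condition shift applied to
#'   the upstream node of each perturbed edge.
#' @slot design integer vector \code{c(lines, conditions, replicates)}.
#' @slot seed integer, generator seed.
#'
#' @export
setClass("GroundTruth",
  representation(
    edges = "data.frame",
    genes = "character",
    sigma = "numeric",
    baseline = "numeric",
    perturbed = "data.frame",
    shift = "numeric",
    design = "integer",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (any(object@sigma <= 0)) msg <- c(msg, "all noise sigmas must be > 0")
  if (nrow(object@perturbed)) {
    key <- function(d) paste(d$parent, d$child, sep = "\r")
    if (!all(key(object@perturbed) %in% key(object@edges)))
      msg <- c(msg, "perturbed edges must be a subset of the network edges")
  }
  if (length(object@design) != 3L || any(object@design < 1L))
    msg <- c(msg, "design must be c(lines, conditions, replicates), all >= 1")
  if (length(msg)) msg else TRUE
})

#' Expression data: samples by genes with sample annotations
#'
#' A numeric matrix of (log2-scale) expression with samples in rows and genes
#' in columns, plus a sample annotation table (condition, line, ...). Most
#' functions in the package also accept a bare matrix with dimnames.
#'
#' @slot values numeric matrix, samples by genes, with dimnames.
#' @slot sampleInfo data.frame of per-sample annotations, rownames matching
#'   the matrix rows.
#'
#' @export
setClass("ExpressionData",
  representation(
    values = "matrix",
    sampleInfo = "data.frame"
  )
)

setValidity("ExpressionData", function(object) {
  msg <- character()
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "expression matrix must have sample and gene names")
  else {
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate sample identifiers")
  }
  if (any(!is.finite(v))) msg <- c(msg, "expression values must be finite")
  if (nrow(object@sampleInfo) && !identical(rownames(object@sampleInfo), rownames(v)))
    msg <- c(msg, "sampleInfo rownames must match the sample order")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn ExpressionData-class the samples-by-genes value matrix.
#' @param x object.
#' @export
exprValues <- function(x) {
  if (is(x, "ExpressionData")) x@values
  else if (is.matrix(x)) x
  else stop("expected an ExpressionData or a samples-by-genes matrix")
}

#' @describeIn ExpressionData-class per-sample annotation table.
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "ExpressionData"))
  x@sampleInfo
}

#' Construct an ExpressionData object
#'
#' @param values samples-by-genes numeric matrix with dimnames.
#' @param sampleInfo optional per-sample annotation data.frame.
#' @return An [ExpressionData-class] object.
#' @export
expressionData <- function(values, sampleInfo = NULL) {
  if (is.null(sampleInfo))
    sampleInfo <- data.frame(row.names = rownames(values))
  new("ExpressionData", values = values, sampleInfo = sampleInfo)
}

#' Edge identifier strings of a network-like object
#'
#' @param x a \code{BasalNetwork}, \code{Subnetwork}, \code{ModelSet},
#'   \code{EcvMatrix}, \code{EdgeFrequencyNetwork} or edge data.frame.
#' @return character vector \code{"parent->child"}.
#' @export
edgeIds <- function(x) {
  e <- networkEdges(x)
  if (!nrow(e)) return(character())
  paste0(e$parent, "->", e$child)
}

#' Edge table of a network-like object
#'
#' @param x object holding directed edges.
#' @return data.frame with at least columns \code{parent} and \code{child}.
#' @export
networkEdges <- function(x) {
  if (is.data.frame(x)) x
  else if (is(x, "BasalNetwork") || is(x, "Subnetwork") ||
           is(x, "EdgeFrequencyNetwork") || is(x, "ModelSet") ||
           is(x, "EcvMatrix") || is(x, "GroundTruth")) x@edges
  else stop("no edge table for objects of class ", class(x)[1])
}

#' Gene universe of a network-like object
#'
#' @param x object holding a gene set.
#' @return character vector of gene identifiers.
#' @export
networkGenes <- function(x) {
  if (is(x, "Subnetwork")) x@nodes else x@genes
}

#' ECv value matrix
#'
#' @param x an [EcvMatrix-class].
#' @return numeric samples-by-edges matrix.
#' @export
ecvValues <- function(x) {
  stopifnot(is(x, "EcvMatrix"))
  x@values
}

## ---- show methods ----

setMethod("show", "SplineBasis", function(object) {
  cat(sprintf("Clamped cubic B-spline basis: M = %d on [%.4g, %.4g]\n",
              object@M, object@supportLo, object@supportHi))
})

setMethod("show", "ScoreConfig", function(object) {
  cat(sprintf("ScoreConfig: M = %d, lambda grid {%s}, ridge %.1e, max parents %d\n",
              object@M, paste(object@lambdaGrid, collapse = ", "),
              object@ridgeEps, object@maxParents))
})

setMethod("show", "LocalModel", function(object) {
  if (length(object@parents))
    cat(sprintf("LocalModel: %s ~ %s (sigma2 = %.4g, n = %d)\n", object@child,
                paste(object@parents, collapse = " + "), object@sigma2,
                object@nTrain))
  else
    cat(sprintf("LocalModel: %s ~ constant %.4g (sigma2 = %.4g, n = %d)\n",
                object@child, object@constant, object@sigma2, object@nTrain))
})

setMethod("show", "ModelSet", function(object) {
  cat(sprintf("ModelSet: %d genes, %d edges, %d fitted local models\n",
              length(object@genes), nrow(object@edges), length(object@models)))
})

setMethod("show", "EdgeFrequencyNetwork", function(object) {
  cat(sprintf("EdgeFrequencyNetwork: %d genes, %d observed edges (T = %d, subset size %d)\n",
              length(object@genes), nrow(object@edges), object@tIter,
              object@subsetSize))
})

setMethod("show", "BasalNetwork", function(object) {
  cat(sprintf("BasalNetwork: %d genes, %d directed edges\n",
              length(object@genes), nrow(object@edges)))
})

setMethod("show", "EcvMatrix", function(object) {
  cat(sprintf("EcvMatrix: %d samples x %d edges\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "Subnetwork", function(object) {
  tab <- table(factor(object@edges$origin,
                      levels = c("delta_extracted", "basal_fill")))
  cat(sprintf("Subnetwork: %d nodes, %d edges (%d extracted + %d basal fill)\n",
              length(object@nodes), nrow(object@edges),
              tab[["delta_extracted"]], tab[["basal_fill"]]))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d genes, %d edges, %d perturbed (shift %.2g), design %d lines x %d conditions x %d replicates\n",
    length(object@genes), nrow(object@edges), nrow(object@perturbed),
    object@shift, object@design[1], object@design[2], object@design[3]))
})

setMethod("show", "ExpressionData", function(object) {
  cat(sprintf("ExpressionData: %d samples x %d genes", nrow(object@values),
              ncol(object@values)))
  if (ncol(object@sampleInfo))
    cat(sprintf(" (annotations: %s)", paste(names(object@sampleInfo),
                                            collapse = ", ")))
  cat("\n")
})
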