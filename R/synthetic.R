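## Seeded synthetic-data generator. Emulates the study design the package
## targets: a small gene network observed across cell lines x conditions x
## replicates, with additive nonlinear parent-to-child transmission,
## Gaussian noise, a designated set of condition-responsive edges, and
## survival outcomes whose hazard depends on group membership.

.geneNames <- function(p) sprintf("g%02d", seq_len(p))

#' Random directed acyclic graph
#'
#' Edges are drawn only from lower to higher topological index (acyclic by
#' construction), capped at \code{maxParents} per child, then node labels
#' are shuffled so the index order carries no information.
#'
#' @param p number of genes.
#' @param maxParents cap on parents per child.
#' @param edgeProb probability of each admissible parent-child edge.
#' @param seed integer seed.
#' @return A [BasalNetwork-class] DAG over genes \code{g01..gNN}.
#' @export
randomDag <- function(p, maxParents = 3L, edgeProb = 0.3, seed = 1L) {
  stopifnot(p >= 1L, edgeProb >= 0, edgeProb <= 1)
  set.seed(seed)
  genes <- .geneNames(p)
  label <- sample(genes)  # topological position -> label
  parent <- character()
  child <- character()
  for (j in seq_len(p)[-1]) {
    cand <- seq_len(j - 1L)
    pick <- cand[stats::runif(length(cand)) < edgeProb]
    if (length(pick) > maxParents)
      pick <- sort(sample(pick, maxParents))
    for (u in pick) {
      parent <- c(parent, label[u])
      child <- c(child, label[j])
    }
  }
  ord <- order(parent, child)
  .basalNetwork(genes, parent[ord], child[ord])
}

.edgeFunction <- function(family, a, b) {
  switch(family,
    linear = function(x) a * (x - b),
    sigmoid = function(x) a * (2 / (1 + exp(-1.5 * (x - b))) - 1),
    sine = function(x) a * sin(1.2 * (x - b)),
    quadratic = function(x) a * ((x - b)^2 - 1),
    stop("unknown edge function family: ", family))
}

#' Construct a ground-truth network for simulation
#'
#' Builds a random DAG over \code{p - 2 * nPerturbed} core genes with
#' transmission functions drawn from the linear / sigmoid / sine /
#' quadratic families, then appends \code{nPerturbed} disjoint
#' regulator-target pairs carrying the condition-responsive edges: each
#' pair is a root regulator wired to a dedicated target through a
#' unit-slope linear transmission. In the treated condition the regulator's
#' baseline shifts by \code{shift}, so the designated edge's true component
#' difference between conditions equals \code{shift} — samples move along
#' the transmission curve, which is the signal the edge-contribution
#' machinery detects. Root genes vary with standard deviation
#' \code{rootSd} around their baseline (their biological replicate
#' variability); non-root noise is \code{sigma}.
#'
#' @param p total number of genes (at least \code{2 * nPerturbed + 1}).
#' @param nPerturbed number of condition-responsive edges (default 3).
#' @param shift treated-condition shift of the perturbed regulators
#'   (default 2, a four-fold change on the log2 scale).
#' @param sigma Gaussian noise standard deviation of non-root genes
#'   (default 0.3).
#' @param rootSd replicate-level standard deviation of root genes
#'   (default 0.5, a typical log2-scale replicate variability).
#' @param edgeProb edge probability of the core DAG.
#' @param maxParents parent cap of the core DAG.
#' @param lines,conditions,replicates the experimental design (default
#'   3 x 2 x 3, eighteen samples).
#' @param seed integer seed.
#' @return A [GroundTruth-class].
#' @export
makeGroundTruth <- function(p = 10L, nPerturbed = 3L, shift = 2,
                            sigma = 0.3, rootSd = 0.5, edgeProb = 0.35,
                            maxParents = 3L,
                            lines = 3L, conditions = 2L, replicates = 3L,
                            seed = 1L) {
  p <- as.integer(p)
  nPerturbed <- as.integer(nPerturbed)
  pCore <- p - 2L * nPerturbed
  if (pCore < 1L) stop("p must exceed 2 * nPerturbed")
  set.seed(seed)
  genes <- .geneNames(p)
  coreGenes <- genes[seq_len(pCore)]
  dag <- randomDag(pCore, maxParents, edgeProb,
                   seed = sample.int(.Machine$integer.max - 1L, 1L))
  coreEdges <- dag@edges
  coreEdges$parent <- coreGenes[match(coreEdges$parent, dag@genes)]
  coreEdges$child <- coreGenes[match(coreEdges$child, dag@genes)]
  baseline <- stats::setNames(stats::runif(p, 4, 10), genes)
  fams <- c("linear", "sigmoid", "sine", "quadratic")
  nCore <- nrow(coreEdges)
  edges <- data.frame(parent = character(), child = character(),
                      family = character(), a = numeric(), b = numeric(),
                      c = numeric(), stringsAsFactors = FALSE)
  if (nCore) {
    fam <- sample(fams, nCore, replace = TRUE)
    amp <- stats::runif(nCore, 0.75, 1.5) * sample(c(-1, 1), nCore,
                                                   replace = TRUE)
    edges <- data.frame(parent = coreEdges$parent, child = coreEdges$child,
                        family = fam, a = amp,
                        b = unname(baseline[coreEdges$parent]),
                        c = 0, stringsAsFactors = FALSE)
  }
  perturbed <- data.frame(parent = character(), child = character(),
                          stringsAsFactors = FALSE)
  if (nPerturbed > 0L) {
    u <- genes[pCore + seq_len(nPerturbed)]
    v <- genes[pCore + nPerturbed + seq_len(nPerturbed)]
    edges <- rbind(edges,
                   data.frame(parent = u, child = v, family = "linear",
                              a = 1, b = unname(baseline[u]), c = 0,
                              stringsAsFactors = FALSE))
    perturbed <- data.frame(parent = u, child = v, stringsAsFactors = FALSE)
  }
  hasParent <- genes %in% edges$child
  sig <- stats::setNames(ifelse(hasParent, sigma, rootSd), genes)
  new("GroundTruth", edges = edges, genes = genes, sigma = sig,
      baseline = baseline, perturbed = perturbed, shift = shift,
      design = as.integer(c(lines, conditions, replicates)),
      seed = as.integer(seed))
}

#' The true network of a ground truth as a BasalNetwork
#'
#' Convenience for fitting local models on the generative structure itself
#' (bypassing structure search), e.g. when testing the ECv machinery in
#' isolation.
#'
#' @param gt a [GroundTruth-class].
#' @return A [BasalNetwork-class].
#' @export
groundTruthNetwork <- function(gt) {
  stopifnot(is(gt, "GroundTruth"))
  .basalNetwork(gt@genes, gt@edges$parent, gt@edges$child)
}

#' True component value of a ground-truth edge
#'
#' Evaluates the generative transmission function of an edge at given
#' parent expression values (without noise or condition shifts).
#'
#' @param gt a [GroundTruth-class].
#' @param parent,child the edge.
#' @param x parent expression values.
#' @return numeric vector of component values.
#' @export
trueComponent <- function(gt, parent, child, x) {
  i <- which(gt@edges$parent == parent & gt@edges$child == child)
  if (!length(i)) stop("no such edge in the ground truth")
  f <- .edgeFunction(gt@edges$family[i], gt@edges$a[i], gt@edges$b[i])
  f(x)
}

#' Simulate expression data from a ground truth
#'
#' Ancestral sampling in topological order: each gene is its baseline plus
#' a small per-line intercept, plus the sum of its incoming transmission
#' functions applied to the already-sampled parents, plus Gaussian noise.
#' In the treated condition the perturbed regulators' baselines shift by
#' the ground truth's \code{shift}. Values live on a positive, log2-like
#' scale.
#'
#' @param gt a [GroundTruth-class].
#' @param nPerCell replicates per line-condition cell (defaults to the
#'   design's replicate count).
#' @param seed integer seed.
#' @param lineSd standard deviation of per-line, per-gene intercepts
#'   (default 0.15).
#' @return An [ExpressionData-class] with sample annotations
#'   \code{condition} (\code{"control"} / \code{"treated"}), \code{line}
#'   and \code{replicate}.
#' @export
simulateExpression <- function(gt, nPerCell = NULL, seed = 1L,
                               lineSd = 0.15) {
  stopifnot(is(gt, "GroundTruth"))
  L <- gt@design[1]
  C <- gt@design[2]
  R <- if (is.null(nPerCell)) gt@design[3] else as.integer(nPerCell)
  p <- length(gt@genes)
  set.seed(seed)
  lineOffset <- matrix(stats::rnorm(L * p, 0, lineSd), L, p,
                       dimnames = list(NULL, gt@genes))
  topo <- .topoOrder(gt)
  condNames <- c("control", "treated")[seq_len(C)]
  shiftGenes <- unique(gt@perturbed$parent)
  n <- L * C * R
  vals <- matrix(NA_real_, n, p, dimnames = list(NULL, gt@genes))
  info <- data.frame(condition = character(n), line = character(n),
                     replicate = integer(n), stringsAsFactors = FALSE)
  edgesByChild <- split(seq_len(nrow(gt@edges)), gt@edges$child)
  row <- 0L
  sampleNames <- character(n)
  for (l in seq_len(L)) {
    for (ci in seq_len(C)) {
      idx <- row + seq_len(R)
      block <- matrix(NA_real_, R, p, dimnames = list(NULL, gt@genes))
      for (g in topo) {
        mu <- gt@baseline[g] + lineOffset[l, g]
        if (ci == 2L && g %in% shiftGenes) mu <- mu + gt@shift
        contrib <- rep(0, R)
        for (ei in edgesByChild[[g]]) {
          f <- .edgeFunction(gt@edges$family[ei], gt@edges$a[ei],
                             gt@edges$b[ei])
          contrib <- contrib + f(block[, gt@edges$parent[ei]])
        }
        block[, g] <- mu + contrib + stats::rnorm(R, 0, gt@sigma[g])
      }
      vals[idx, ] <- block
      info$condition[idx] <- condNames[ci]
      info$line[idx] <- paste0("line", l)
      info$replicate[idx] <- seq_len(R)
      sampleNames[idx] <- paste0("line", l, "_", condNames[ci], "_r",
                                 seq_len(R))
      row <- row + R
    }
  }
  rownames(vals) <- sampleNames
  rownames(info) <- sampleNames
  expressionData(vals, info)
}

.topoOrder <- function(gt) {
  genes <- gt@genes
  indeg <- stats::setNames(integer(length(genes)), genes)
  tab <- table(gt@edges$child)
  indeg[names(tab)] <- as.integer(tab)
  childrenOf <- split(gt@edges$child, gt@edges$parent)
  queue <- sort(genes[indeg == 0L])
  out <- character()
  while (length(queue)) {
    g <- queue[1]
    queue <- queue[-1]
    out <- c(out, g)
    for (ch in childrenOf[[g]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(out) != length(genes)) stop("ground-truth network is cyclic")
  out
}

#' Simulate survival records with group-dependent hazard
#'
#' Exponential event times with hazard \code{baselineHazard} in the first
#' group and \code{baselineHazard * hazardRatio} in the second, with
#' independent exponential censoring calibrated so that a fraction of about
#' \code{censorRate} of first-group subjects is censored
#' (\code{censorRate = 0} yields no censoring).
#'
#' @param groups two-level factor (or vector) of group membership, named by
#'   sample (unnamed vectors get \code{s1..sn}).
#' @param baselineHazard events per day in the reference group (default
#'   1/1000).
#' @param hazardRatio hazard multiplier of the second group (default 2).
#' @param censorRate target censoring fraction in the reference group
#'   (default 0.3).
#' @param seed integer seed.
#' @return data.frame with columns \code{sample}, \code{time}, \code{event}
#'   and \code{group}.
#' @export
simulateSurvival <- function(groups, baselineHazard = 0.001,
                             hazardRatio = 2, censorRate = 0.3, seed = 1L) {
  if (hazardRatio <= 0) stop("hazardRatio must be > 0")
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must lie in [0, 1)")
  g <- factor(groups)
  n <- length(g)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("s", seq_len(n))
  set.seed(seed)
  hz <- baselineHazard * ifelse(as.integer(g) == 2L, hazardRatio, 1)
  eventTime <- stats::rexp(n, hz)
  if (censorRate > 0) {
    ch <- baselineHazard * censorRate / (1 - censorRate)
    censTime <- stats::rexp(n, ch)
  } else {
    censTime <- rep(Inf, n)
  }
  data.frame(sample = nm, time = pmin(eventTime, censTime),
             event = as.integer(eventTime <= censTime),
             group = as.character(g), stringsAsFactors = FALSE)
}
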