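## Structure search over directed gene networks. Exact dynamic-programming
## search and greedy hill climbing share the local score; the
## iterated-subnetwork estimator aggregates greedy searches on sampled gene
## subsets into per-edge frequencies.

#' Construct a basal network from an explicit edge list
#'
#' @param genes gene universe.
#' @param parent,child equal-length character vectors of directed edges.
#' @param frequency optional per-edge frequency.
#' @return A [BasalNetwork-class].
#' @examples
#' basalNetwork(c("a", "b", "c"), parent = c("a", "b"), child = c("b", "c"))
#' @export
basalNetwork <- function(genes, parent = character(), child = character(),
                         frequency = rep(NA_real_, length(parent))) {
  .basalNetwork(genes, parent, child, frequency)
}

.basalNetwork <- function(genes, parent = character(), child = character(),
                          frequency = rep(NA_real_, length(parent))) {
  new("BasalNetwork", genes = as.character(genes),
      edges = data.frame(parent = as.character(parent),
                         child = as.character(child),
                         frequency = as.numeric(frequency),
                         stringsAsFactors = FALSE))
}

## Reachability from -> to over a children adjacency list (integer indexed).
.reachable <- function(childrenOf, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(length(childrenOf))
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in childrenOf[[v]]) {
      if (w == to) return(TRUE)
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  FALSE
}

## Greedy hill climb over add/delete/reverse moves among `nodes` (global
## gene indices into the cache). Returns list(parents = named list of
## integer vectors keyed by node index as character).
.hillClimb <- function(cache, nodes, cfg, init = NULL) {
  nodes <- sort(nodes)
  nn <- length(nodes)
  maxPar <- cfg@maxParents
  pa <- if (is.null(init)) rep(list(integer()), cache$p) else init
  childrenOf <- rep(list(integer()), cache$p)
  for (v in nodes)
    for (u in pa[[v]]) childrenOf[[u]] <- c(childrenOf[[u]], v)
  sc <- numeric(cache$p)
  for (v in nodes) sc[v] <- .cachedScore(cache, v, pa[[v]])
  improve <- TRUE
  guard <- 0L
  while (improve && guard < 100L * nn) {
    guard <- guard + 1L
    improve <- FALSE
    bestDelta <- 1e-9
    bestMove <- NULL
    for (ia in seq_len(nn)) {
      a <- nodes[ia]
      for (ib in seq_len(nn)) {
        if (ia == ib) next
        b <- nodes[ib]
        hasEdge <- a %in% pa[[b]]
        if (!hasEdge) {
          if (length(pa[[b]]) >= maxPar) next
          if (.reachable(childrenOf, b, a)) next  # would close a cycle
          d <- .cachedScore(cache, b, c(pa[[b]], a)) - sc[b]
          if (d > bestDelta) {
            bestDelta <- d
            bestMove <- list(op = "add", a = a, b = b)
          }
        } else {
          paDrop <- setdiff(pa[[b]], a)
          scDrop <- .cachedScore(cache, b, paDrop)
          d <- scDrop - sc[b]
          if (d > bestDelta) {
            bestDelta <- d
            bestMove <- list(op = "del", a = a, b = b)
          }
          if (length(pa[[a]]) < maxPar) {
            childrenOf[[a]] <- setdiff(childrenOf[[a]], b)
            cyc <- .reachable(childrenOf, a, b)
            childrenOf[[a]] <- c(childrenOf[[a]], b)
            if (!cyc) {
              d2 <- (scDrop - sc[b]) +
                (.cachedScore(cache, a, c(pa[[a]], b)) - sc[a])
              if (d2 > bestDelta) {
                bestDelta <- d2
                bestMove <- list(op = "rev", a = a, b = b)
              }
            }
          }
        }
      }
    }
    if (!is.null(bestMove)) {
      improve <- TRUE
      a <- bestMove$a
      b <- bestMove$b
      if (bestMove$op == "add") {
        pa[[b]] <- c(pa[[b]], a)
        childrenOf[[a]] <- c(childrenOf[[a]], b)
      } else if (bestMove$op == "del") {
        pa[[b]] <- setdiff(pa[[b]], a)
        childrenOf[[a]] <- setdiff(childrenOf[[a]], b)
      } else {
        pa[[b]] <- setdiff(pa[[b]], a)
        childrenOf[[a]] <- setdiff(childrenOf[[a]], b)
        pa[[a]] <- c(pa[[a]], b)
        childrenOf[[b]] <- c(childrenOf[[b]], a)
      }
      sc[b] <- .cachedScore(cache, b, pa[[b]])
      sc[a] <- .cachedScore(cache, a, pa[[a]])
    }
  }
  list(parents = pa, nodes = nodes, totalScore = sum(sc[nodes]))
}

## Perturb-and-restart wrapper: re-climbs from randomly perturbed copies of
## the incumbent (a few random feasible reversals/deletions), keeping the
## best-scoring result. Uses the current RNG stream; memoized scores make
## restarts cheap.
.climbWithRestarts <- function(cache, nodes, cfg, restarts = 2L,
                               perturb = 2L) {
  best <- .hillClimb(cache, nodes, cfg)
  for (r in seq_len(restarts)) {
    pa <- best$parents
    for (m in seq_len(perturb)) {
      edges <- do.call(rbind, lapply(nodes, function(v) {
        if (length(pa[[v]])) cbind(pa[[v]], v) else NULL
      }))
      if (is.null(edges) || !nrow(edges)) break
      i <- sample.int(nrow(edges), 1L)
      a <- edges[i, 1L]
      b <- edges[i, 2L]
      pa[[b]] <- setdiff(pa[[b]], a)
      ## try to reverse; fall back to plain deletion if infeasible
      childrenOf <- rep(list(integer()), cache$p)
      for (v in nodes) for (u in pa[[v]])
        childrenOf[[u]] <- c(childrenOf[[u]], v)
      if (length(pa[[a]]) < cfg@maxParents &&
          !.reachable(childrenOf, a, b))
        pa[[a]] <- c(pa[[a]], b)
    }
    cand <- .hillClimb(cache, nodes, cfg, init = pa)
    if (cand$totalScore > best$totalScore + 1e-9) best <- cand
  }
  best
}

.parentsToNetwork <- function(cache, climb) {
  parent <- character()
  child <- character()
  for (v in climb$nodes) {
    for (u in sort(climb$parents[[v]])) {
      parent <- c(parent, cache$genes[u])
      child <- c(child, cache$genes[v])
    }
  }
  .basalNetwork(cache$genes[climb$nodes], parent, child)
}

#' Exact structure search over all DAGs (small gene sets)
#'
#' Finds the directed acyclic graph maximizing the sum of local
#' marginal-likelihood scores (uniform structure prior) by dynamic
#' programming over node orderings. Intended as the exact reference for
#' small problems; the cost is exponential in the number of genes.
#'
#' @param X an [ExpressionData-class] or samples-by-genes matrix.
#' @param cfg a [ScoreConfig-class].
#' @param maxNodes guard on problem size (at most 5 by default).
#' @return A [BasalNetwork-class] that is a DAG.
#' @export
exhaustiveSearch <- function(X, cfg = scoreConfig(), maxNodes = 5L) {
  v <- .asExprMatrix(X)
  p <- ncol(v)
  if (p > maxNodes)
    stop("size error: exhaustive search limited to ", maxNodes, " genes")
  cache <- .scoreCache(v, cfg)
  full <- bitwShiftL(1L, p) - 1L
  ## best parent set per child given an availability mask, candidates
  ## enumerated by size then lexicographic order so ties prefer fewer,
  ## lexicographically earlier parents
  subsetsOf <- function(idx, maxSize) {
    out <- list(integer())
    for (size in seq_len(min(maxSize, length(idx)))) {
      if (size > length(idx)) break
      cmb <- utils::combn(idx, size, simplify = FALSE)
      out <- c(out, cmb)
    }
    out
  }
  maskOf <- function(s) {
    m <- 0L
    for (x in s) m <- bitwOr(m, bitwShiftL(1L, x - 1L))
    m
  }
  bestScore <- vector("list", p)
  bestSet <- vector("list", p)
  for (j in seq_len(p)) {
    cand <- subsetsOf(setdiff(seq_len(p), j), cfg@maxParents)
    candMask <- vapply(cand, maskOf, integer(1))
    candScore <- vapply(cand, function(s) .cachedScore(cache, j, s), numeric(1))
    bs <- rep(-Inf, full + 1L)
    bset <- vector("list", full + 1L)
    for (mask in 0:full) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) next
      ok <- bitwAnd(candMask, mask) == candMask
      sc <- candScore[ok]
      cs <- cand[ok]
      ix <- which.max(sc)  # first max: smallest/lex-earliest subset wins ties
      bs[mask + 1L] <- sc[ix]
      bset[[mask + 1L]] <- cs[[ix]]
    }
    bestScore[[j]] <- bs
    bestSet[[j]] <- bset
  }
  dp <- rep(-Inf, full + 1L)
  dpSink <- rep(NA_integer_, full + 1L)
  dp[1L] <- 0
  for (mask in 1:full) {
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L) next
      rest <- bitwAnd(mask, bitwNot(bit))
      val <- dp[rest + 1L] + bestScore[[j]][rest + 1L]
      if (val > dp[mask + 1L]) {
        dp[mask + 1L] <- val
        dpSink[mask + 1L] <- j
      }
    }
  }
  parent <- character()
  child <- character()
  mask <- full
  while (mask > 0L) {
    j <- dpSink[mask + 1L]
    rest <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
    for (u in sort(bestSet[[j]][[rest + 1L]])) {
      parent <- c(parent, cache$genes[u])
      child <- c(child, cache$genes[j])
    }
    mask <- rest
  }
  ord <- order(parent, child)
  .basalNetwork(cache$genes, parent[ord], child[ord])
}

#' Total network score (sum of local scores) of a directed network
#'
#' @param X expression data the network was learned from.
#' @param network a [BasalNetwork-class].
#' @param cfg a [ScoreConfig-class].
#' @return single numeric total score.
#' @export
networkScore <- function(X, network, cfg = scoreConfig()) {
  v <- .asExprMatrix(X)
  cache <- .scoreCache(v[, network@genes, drop = FALSE], cfg)
  parentMap <- split(network@edges$parent, network@edges$child)
  tot <- 0
  for (g in network@genes) {
    pa <- parentMap[[g]]
    pi <- if (is.null(pa)) integer() else .geneIndex(cache, pa)
    tot <- tot + .cachedScore(cache, .geneIndex(cache, g), pi)
  }
  tot
}

#' Greedy hill-climbing structure search
#'
#' Starting from the empty graph, repeatedly applies the single
#' add/delete/reverse edge move that most improves the total score, under
#' acyclicity and the parent-count cap, until no move improves. The search
#' is deterministic: moves are scanned in a fixed order and the first of any
#' exactly tied improvements is taken.
#'
#' After the first climb converges, the search restarts a few times from
#' randomly perturbed copies of the incumbent (seeded, so reproducible) and
#' keeps the best-scoring result, which escapes most small local optima.
#'
#' @inheritParams exhaustiveSearch
#' @param seed integer seed driving the restart perturbations.
#' @param restarts number of perturb-and-restart rounds (default 2).
#' @return A [BasalNetwork-class] that is a DAG.
#' @export
greedyHillClimb <- function(X, cfg = scoreConfig(), seed = 1L,
                            restarts = 2L) {
  v <- .asExprMatrix(X)
  cache <- .scoreCache(v, cfg)
  set.seed(seed)
  climb <- .climbWithRestarts(cache, seq_len(cache$p), cfg,
                              restarts = restarts)
  .parentsToNetwork(cache, climb)
}

#' Iterated-subnetwork edge-frequency estimation
#'
#' Repeats \code{tIter} times: pick a seed gene uniformly at random, grow a
#' candidate gene subset by absolute-correlation-weighted neighbor sampling
#' up to \code{subsetSize} genes, estimate a subnetwork on the subset by
#' greedy hill climbing, and record its edges. Each directed edge's
#' frequency is the number of estimated subnetworks containing it divided by
#' the number of sampled subsets containing both of its endpoints, so
#' rarely co-sampled pairs are not penalized. All randomness flows from
#' \code{seed} through per-iteration substreams, so results are reproducible
#' and independent of execution order.
#'
#' @param X an [ExpressionData-class] or samples-by-genes matrix.
#' @param tIter number of subnetwork estimations (>= 1).
#' @param subsetSize genes per sampled subset (default 30, capped at the
#'   number of genes).
#' @param cfg a [ScoreConfig-class].
#' @param seed integer seed.
#' @return An [EdgeFrequencyNetwork-class].
#' @seealso [thresholdNetwork()] to obtain the basal network.
#' @export
nnsrEstimate <- function(X, tIter, subsetSize = 30L, cfg = scoreConfig(),
                         seed = 1L) {
  tIter <- as.integer(tIter)
  if (is.na(tIter) || tIter < 1L)
    stop("invalid iteration count: tIter must be >= 1")
  v <- .asExprMatrix(X)
  p <- ncol(v)
  subsetSize <- as.integer(min(subsetSize, p))
  if (subsetSize < 2L) stop("subsetSize must be at least 2")
  cache <- .scoreCache(v, cfg)
  aff <- abs(stats::cor(v))
  aff[!is.finite(aff)] <- 0
  diag(aff) <- 0
  set.seed(seed)
  iterSeeds <- sample.int(.Machine$integer.max - 1L, tIter, replace = TRUE)
  edgeCount <- new.env(parent = emptyenv())
  pairCount <- new.env(parent = emptyenv())
  bump <- function(env, key) {
    cur <- env[[key]]
    env[[key]] <- if (is.null(cur)) 1L else cur + 1L
  }
  for (t in seq_len(tIter)) {
    set.seed(iterSeeds[t])
    cur <- sample.int(p, 1L)
    while (length(cur) < subsetSize) {
      w <- if (length(cur) == 1L) aff[cur, ] else colSums(aff[cur, , drop = FALSE])
      w[cur] <- 0
      if (sum(w) <= 0) {
        rest <- setdiff(seq_len(p), cur)
        nxt <- if (length(rest) == 1L) rest else rest[sample.int(length(rest), 1L)]
      } else {
        nxt <- sample.int(p, 1L, prob = w)
      }
      cur <- c(cur, nxt)
    }
    cur <- sort(cur)
    for (i in seq_len(length(cur) - 1L))
      for (j in (i + 1L):length(cur))
        bump(pairCount, paste0(cur[i], ",", cur[j]))
    climb <- .climbWithRestarts(cache, cur, cfg)
    for (b in climb$nodes)
      for (a in climb$parents[[b]])
        bump(edgeCount, paste0(a, ">", b))
  }
  ekeys <- ls(edgeCount)
  if (length(ekeys)) {
    parts <- strsplit(ekeys, ">", fixed = TRUE)
    ai <- as.integer(vapply(parts, `[`, character(1), 1L))
    bi <- as.integer(vapply(parts, `[`, character(1), 2L))
    cnt <- vapply(ekeys, function(k) edgeCount[[k]], integer(1))
    cos <- vapply(seq_along(ai), function(i) {
      pairCount[[paste0(min(ai[i], bi[i]), ",", max(ai[i], bi[i]))]]
    }, integer(1))
    edges <- data.frame(parent = cache$genes[ai], child = cache$genes[bi],
                        count = cnt, cosampled = cos,
                        frequency = cnt / cos, stringsAsFactors = FALSE)
    edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(parent = character(), child = character(),
                        count = integer(), cosampled = integer(),
                        frequency = numeric(), stringsAsFactors = FALSE)
  }
  pkeys <- ls(pairCount)
  if (length(pkeys)) {
    parts <- strsplit(pkeys, ",", fixed = TRUE)
    g1 <- as.integer(vapply(parts, `[`, character(1), 1L))
    g2 <- as.integer(vapply(parts, `[`, character(1), 2L))
    pairs <- data.frame(gene1 = cache$genes[g1], gene2 = cache$genes[g2],
                        cosampled = vapply(pkeys, function(k) pairCount[[k]],
                                           integer(1)),
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$gene1, pairs$gene2), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(gene1 = character(), gene2 = character(),
                        cosampled = integer(), stringsAsFactors = FALSE)
  }
  new("EdgeFrequencyNetwork", genes = cache$genes, edges = edges,
      pairs = pairs, tIter = tIter, subsetSize = subsetSize,
      seed = as.integer(seed))
}

#' Co-sample count of a gene pair
#'
#' How many sampled subsets contained both genes; 0 for pairs never sampled
#' together (whose edge frequency is undefined and treated as 0).
#'
#' @param freqNet an [EdgeFrequencyNetwork-class].
#' @param gene1,gene2 gene identifiers.
#' @return integer count.
#' @export
cosampleCount <- function(freqNet, gene1, gene2) {
  stopifnot(is(freqNet, "EdgeFrequencyNetwork"))
  a <- min(gene1, gene2)
  b <- max(gene1, gene2)
  hit <- freqNet@pairs$gene1 == a & freqNet@pairs$gene2 == b
  if (any(hit)) freqNet@pairs$cosampled[which(hit)[1]] else 0L
}

#' Threshold edge frequencies into the basal network
#'
#' Keeps edges whose frequency exceeds \code{cutoff}. If both directions of
#' a gene pair survive, only the higher-frequency direction is kept (exact
#' ties resolved toward the lexicographically smaller edge). The result is a
#' directed graph that may contain cycles; downstream model fitting is
#' per-child and does not require global acyclicity.
#'
#' @param freqNet an [EdgeFrequencyNetwork-class].
#' @param cutoff frequency cutoff in (0, 1]; edges with frequency strictly
#'   greater are kept (default 0.1).
#' @return A [BasalNetwork-class].
#' @export
thresholdNetwork <- function(freqNet, cutoff = 0.1) {
  stopifnot(is(freqNet, "EdgeFrequencyNetwork"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1)
    stop("parameter error: cutoff must lie in (0, 1]")
  e <- freqNet@edges
  e <- e[e$frequency > cutoff, , drop = FALSE]
  if (nrow(e)) {
    pairKey <- paste(pmin(e$parent, e$child), pmax(e$parent, e$child),
                     sep = "\r")
    keep <- logical(nrow(e))
    for (k in unique(pairKey)) {
      idx <- which(pairKey == k)
      if (length(idx) == 1L) {
        keep[idx] <- TRUE
      } else {
        f <- e$frequency[idx]
        ids <- paste(e$parent[idx], e$child[idx], sep = "\r")
        best <- idx[order(-f, ids)][1]
        keep[best] <- TRUE
      }
    }
    e <- e[keep, , drop = FALSE]
    e <- e[order(e$parent, e$child), , drop = FALSE]
  }
  .basalNetwork(freqNet@genes, e$parent, e$child, e$frequency)
}

#' Concordance between two directed networks
#'
#' Direction-sensitive overlap: the number of edges present in both networks
#' divided by the number of edges in their union. Two identical networks
#' (including two empty ones) have concordance 1.
#'
#' @param netA,netB [BasalNetwork-class] objects over the same gene universe.
#' @return numeric in [0, 1].
#' @export
concordance <- function(netA, netB) {
  stopifnot(is(netA, "BasalNetwork"), is(netB, "BasalNetwork"))
  if (!setequal(netA@genes, netB@genes))
    stop("mismatch error: networks have different gene universes")
  ea <- edgeIds(netA)
  eb <- edgeIds(netB)
  u <- union(ea, eb)
  if (!length(u)) return(1)
  length(intersect(ea, eb)) / length(u)
}

## ---- network file formats ----

#' Write an edge-frequency table as TSV
#'
#' Columns: parent, child, count, cosample_count, frequency.
#'
#' @param freqNet an [EdgeFrequencyNetwork-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeFrequencies <- function(freqNet, path) {
  stopifnot(is(freqNet, "EdgeFrequencyNetwork"))
  e <- freqNet@edges
  out <- data.frame(parent = e$parent, child = e$child, count = e$count,
                    cosample_count = e$cosampled,
                    frequency = sprintf("%.10g", e$frequency),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-frequency table written by [writeEdgeFrequencies()]
#'
#' @param path TSV path.
#' @param genes optional gene universe; defaults to the genes present in the
#'   table.
#' @return An [EdgeFrequencyNetwork-class] (tIter/subsetSize/seed are not
#'   stored in the table and are set to NA-like placeholders).
#' @export
readEdgeFrequencies <- function(path, genes = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  edges <- data.frame(parent = as.character(d$parent),
                      child = as.character(d$child),
                      count = as.integer(d$count),
                      cosampled = as.integer(d$cosample_count),
                      frequency = as.numeric(d$frequency),
                      stringsAsFactors = FALSE)
  if (is.null(genes)) genes <- sort(unique(c(edges$parent, edges$child)))
  pairs <- data.frame(gene1 = pmin(edges$parent, edges$child),
                      gene2 = pmax(edges$parent, edges$child),
                      cosampled = edges$cosampled, stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(paste(pairs$gene1, pairs$gene2, sep = "\r")), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  new("EdgeFrequencyNetwork", genes = as.character(genes), edges = edges,
      pairs = pairs, tIter = 0L, subsetSize = 0L, seed = 0L)
}

#' Write a network edge list as TSV
#'
#' Columns: parent, child, frequency (empty for searches that do not
#' estimate frequencies).
#'
#' @param net a [BasalNetwork-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNetworkTsv <- function(net, path) {
  stopifnot(is(net, "BasalNetwork"))
  e <- net@edges
  out <- data.frame(parent = e$parent, child = e$child,
                    frequency = ifelse(is.na(e$frequency), "",
                                       sprintf("%.10g", e$frequency)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge-list TSV written by [writeNetworkTsv()]
#'
#' @param path TSV path.
#' @param genes optional gene universe.
#' @return A [BasalNetwork-class].
#' @export
readNetworkTsv <- function(path, genes = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character"))
  freq <- suppressWarnings(as.numeric(d$frequency))
  if (is.null(genes)) genes <- sort(unique(c(d$parent, d$child)))
  .basalNetwork(genes, d$parent, d$child, freq)
}

#' Write a network in SIF format
#'
#' One line per edge: \code{parent<TAB>regulates<TAB>child}, the simple
#' interaction format consumed by common network viewers.
#'
#' @param net a [BasalNetwork-class] or [Subnetwork-class].
#' @param path output path.
#' @param relation interaction label (default \code{"regulates"}).
#' @return \code{path}, invisibly.
#' @export
writeNetworkSif <- function(net, path, relation = "regulates") {
  e <- networkEdges(net)
  lines <- if (nrow(e)) paste(e$parent, relation, e$child, sep = "\t")
  else character()
  writeLines(lines, path)
  invisible(path)
}
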