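test_that("exhaustive search handles trivial and dependent systems", {
  X1 <- cbind(a = rnorm(20))
  rownames(X1) <- paste0("s", 1:20)
  expect_equal(nrow(networkEdges(exhaustiveSearch(X1))), 0L)

  X <- linearPairData(200, seed = 11)
  net <- exhaustiveSearch(X)
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)
  expect_setequal(c(e$parent, e$child), c("a", "b"))

  Xbig <- matrix(rnorm(60), 10, 6,
                 dimnames = list(paste0("s", 1:10), letters[1:6]))
  expect_error(exhaustiveSearch(Xbig), "size error")
})

test_that("independent variables yield the empty graph almost always", {
  emptyCount <- 0
  for (r in 1:50) {
    X <- independentPairData(200, seed = 2000 + r)
    if (nrow(networkEdges(exhaustiveSearch(X))) == 0L)
      emptyCount <- emptyCount + 1
  }
  expect_gte(emptyCount, 45)
})

test_that("hill climbing returns acyclic, reproducible graphs", {
  for (r in 1:5) {
    gt <- makeGroundTruth(p = 6, nPerturbed = 0, edgeProb = 0.4,
                          lines = 1, conditions = 1, seed = 300 + r)
    X <- exprValues(simulateExpression(gt, nPerCell = 60, seed = 310 + r))
    net <- greedyHillClimb(X, seed = r)
    e <- networkEdges(net)
    if (nrow(e)) {
      g <- igraph::graph_from_data_frame(e[, c("parent", "child")],
                                         directed = TRUE)
      expect_true(igraph::is_dag(g))
    }
    net2 <- greedyHillClimb(X, seed = r)
    expect_identical(networkEdges(net), networkEdges(net2))
  }
})

test_that("greedy search matches the exact optimum on small instances", {
  matches <- 0
  for (r in 1:20) {
    gt <- makeGroundTruth(p = 4, nPerturbed = 0, edgeProb = 0.5,
                          lines = 1, conditions = 1, seed = 700 + r)
    X <- exprValues(simulateExpression(gt, nPerCell = 150, seed = 800 + r))
    sExact <- networkScore(X, exhaustiveSearch(X))
    sGreedy <- networkScore(X, greedyHillClimb(X, seed = r))
    expect_lte(sGreedy, sExact + 1e-6)  # exact search is an upper bound
    if (abs(sExact - sGreedy) < 1e-6) matches <- matches + 1
  }
  expect_gte(matches, 18)
})

test_that("edge-frequency estimation is seeded and bounded", {
  X <- linearPairData(100, seed = 13)
  f1 <- nnsrEstimate(X, tIter = 20, subsetSize = 2, seed = 5)
  f2 <- nnsrEstimate(X, tIter = 20, subsetSize = 2, seed = 5)
  expect_identical(f1@edges, f2@edges)
  expect_true(all(f1@edges$frequency >= 0 & f1@edges$frequency <= 1))
  # both genes are in every subset; the strong edge must be frequent
  expect_gte(max(f1@edges$frequency), 0.5)
  expect_error(nnsrEstimate(X, tIter = 0), "invalid iteration")
})

test_that("never co-sampled pairs report zero co-sample count", {
  gt <- makeGroundTruth(p = 8, nPerturbed = 0, edgeProb = 0.3,
                        lines = 1, conditions = 1, seed = 17)
  X <- exprValues(simulateExpression(gt, nPerCell = 40, seed = 18))
  fn <- nnsrEstimate(X, tIter = 2, subsetSize = 3, seed = 3)
  sampled <- unique(c(fn@pairs$gene1, fn@pairs$gene2))
  outside <- setdiff(colnames(X), sampled)
  if (length(outside) >= 1L)
    expect_identical(cosampleCount(fn, outside[1], sampled[1]), 0L)
  expect_gte(cosampleCount(fn, fn@pairs$gene1[1], fn@pairs$gene2[1]), 1L)
})

test_that("thresholding keeps the dominant direction", {
  fn <- new("EdgeFrequencyNetwork", genes = c("a", "b", "c"),
            edges = data.frame(parent = c("a", "b", "b"),
                               child = c("b", "a", "c"),
                               count = c(3L, 2L, 1L),
                               cosampled = c(10L, 10L, 10L),
                               frequency = c(0.3, 0.2, 0.1),
                               stringsAsFactors = FALSE),
            pairs = data.frame(gene1 = c("a", "b"), gene2 = c("b", "c"),
                               cosampled = c(10L, 10L),
                               stringsAsFactors = FALSE),
            tIter = 10L, subsetSize = 2L, seed = 1L)
  net <- thresholdNetwork(fn, 0.15)
  e <- networkEdges(net)
  expect_identical(e$parent, "a")
  expect_identical(e$child, "b")
  expect_equal(nrow(networkEdges(thresholdNetwork(fn, 0.9))), 0L)
  expect_equal(nrow(networkEdges(thresholdNetwork(fn, 1.0))), 0L)
  expect_error(thresholdNetwork(fn, 0), "parameter error")
  expect_error(thresholdNetwork(fn, 1.5), "parameter error")
})

test_that("concordance uses the direction-sensitive union denominator", {
  g <- c("a", "b", "c")
  nAB <- basalNetwork(g, parent = c("a", "b"), child = c("b", "c"))
  nA <- basalNetwork(g, parent = "a", child = "b")
  nC <- basalNetwork(g, parent = "c", child = "a")
  expect_equal(concordance(nAB, nAB), 1.0)
  expect_equal(concordance(nA, nC), 0.0)
  expect_equal(concordance(nAB, nA), 0.5)
  expect_equal(concordance(basalNetwork(g), basalNetwork(g)), 1.0)
  nOther <- basalNetwork(c("a", "b"), parent = "a", child = "b")
  expect_error(concordance(nAB, nOther), "mismatch error")
})

test_that("a planted 10-gene structure is mostly recovered at cutoff 0.1", {
  gt <- makeGroundTruth(p = 10, nPerturbed = 0, edgeProb = 0.35,
                        lines = 1, conditions = 1, seed = 11)
  X <- exprValues(simulateExpression(gt, nPerCell = 100, seed = 12))
  fn <- nnsrEstimate(X, tIter = 300, subsetSize = 4, seed = 4)
  net <- thresholdNetwork(fn, 0.1)
  e <- networkEdges(net)
  und <- function(d) unique(paste(pmin(d$parent, d$child),
                                  pmax(d$parent, d$child)))
  trueUnd <- und(networkEdges(groundTruthNetwork(gt)))
  estUnd <- und(e)
  expect_gte(mean(trueUnd %in% estUnd), 0.7)   # recall, direction-blind
  expect_lte(mean(!(estUnd %in% trueUnd)), 0.3)  # false-positive share
})

test_that("edge-frequency and network tables round-trip through TSV", {
  X <- linearPairData(80, seed = 19)
  fn <- nnsrEstimate(X, tIter = 10, subsetSize = 2, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeFrequencies(fn, p1)
  fn2 <- readEdgeFrequencies(p1)
  expect_equal(fn2@edges$frequency, fn@edges$frequency, tolerance = 1e-9)
  expect_identical(fn2@edges$count, fn@edges$count)

  net <- thresholdNetwork(fn, 0.1)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeNetworkTsv(net, p2)
  net2 <- readNetworkTsv(p2)
  expect_identical(networkEdges(net2)$parent, networkEdges(net)$parent)
  p3 <- withr::local_tempfile(fileext = ".sif")
  writeNetworkSif(net, p3)
  expect_true(all(grepl("\tregulates\t", readLines(p3))))
})
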