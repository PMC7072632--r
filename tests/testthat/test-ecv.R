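test_that("ECv equals direct component evaluation", {
  gt <- makeGroundTruth(p = 8, nPerturbed = 2, seed = 31)
  X <- simulateExpression(gt, seed = 32)
  ms <- fitAllModels(exprValues(X), groundTruthNetwork(gt))
  E <- computeEcvMatrix(ms, X)
  v <- exprValues(X)
  expect_equal(dim(ecvValues(E)), c(nrow(v), nrow(ms@edges)))
  for (i in seq_len(nrow(ms@edges))) {
    m <- ms@models[[ms@edges$child[i]]]
    expect_identical(ecvValues(E)[, i],
                     setNames(componentValue(m, ms@edges$k[i],
                                             v[, ms@edges$parent[i]]),
                              rownames(v)))
  }
  expect_error(
    computeEcvMatrix(ms, v[, setdiff(colnames(v), ms@edges$parent[1])]),
    "lookup error")
})

test_that("a noise-free linear edge has the expected contribution", {
  set.seed(33)
  x <- runif(150)
  X <- cbind(a = x, b = 2 * x)
  rownames(X) <- paste0("s", seq_along(x))
  net <- basalNetwork(c("a", "b"), parent = "a", child = "b")
  ms <- fitAllModels(X, net)
  Xq <- rbind(X, q = c(0.5, 1))  # query sample with a = 0.5
  E <- computeEcvMatrix(ms, Xq)
  expect_equal(unname(ecvValues(E)["q", "a->b"]), 1.0, tolerance = 1e-6)
})

test_that("delta-ECv is an absolute mean difference with shift invariance", {
  vals <- matrix(c(2, 2, 0.5, 0.5,
                   1, 3, 2, 2), ncol = 2)
  E <- manualEcvMatrix(vals, parent = c("a", "b"), child = c("x", "y"))
  d <- deltaEcv(E, S = 1:2, T = 3:4)
  expect_equal(unname(d), c(1.5, 0))
  expect_true(all(deltaEcv(E, 1:2, 1:2) == 0))
  # adding a constant to one edge's ECv leaves delta-ECv unchanged
  vals2 <- vals
  vals2[, 1] <- vals2[, 1] + 7.3
  E2 <- manualEcvMatrix(vals2, parent = c("a", "b"), child = c("x", "y"))
  expect_equal(deltaEcv(E2, 1:2, 3:4), d)
  expect_error(deltaEcv(E, integer(), 1:2), "empty-group")
})

test_that("differential edges are extracted by the all/any rules", {
  tab <- data.frame(parent = c("a", "b", "c"), child = c("x", "y", "z"),
                    line1 = c(1.2, 1.2, 0.4), line2 = c(1.1, 0.9, 0.2),
                    line3 = c(1.3, 1.3, 0.1), stringsAsFactors = FALSE)
  allHits <- extractDifferentialEdges(tab, threshold = 1.0, mode = "all")
  expect_identical(allHits$parent, "a")
  anyHits <- extractDifferentialEdges(tab, threshold = 1.0, mode = "any")
  expect_setequal(anyHits$parent, c("a", "b"))
  none <- extractDifferentialEdges(tab, threshold = 2.0)
  expect_equal(nrow(none), 0L)
  expect_error(extractDifferentialEdges(tab, threshold = -1), "positive")
})

test_that("transfer evaluates original models with clamping and accounting", {
  gt <- makeGroundTruth(p = 8, nPerturbed = 2, seed = 41)
  X <- simulateExpression(gt, seed = 42)
  ms <- fitAllModels(exprValues(X), groundTruthNetwork(gt))
  # full gene set: identical to direct computation
  tr <- transferEcv(ms, X)
  expect_identical(ecvValues(tr$ecv), ecvValues(computeEcvMatrix(ms, X)))
  expect_length(tr$report$missingGenes, 0L)

  # drop one parent gene: its edges are dropped and named in the report
  dropGene <- ms@edges$parent[1]
  v2 <- exprValues(X)[, setdiff(colnames(exprValues(X)), dropGene)]
  tr2 <- transferEcv(ms, v2)
  expect_true(dropGene %in% tr2$report$missingGenes)
  expect_true(all(tr2$ecv@edges$parent != dropGene))
  expect_equal(tr2$report$computableEdges + nrow(tr2$report$droppedEdges),
               nrow(ms@edges))
  expect_true(all(tr2$report$droppedEdges$parent == dropGene |
                    tr2$report$droppedEdges$child == dropGene))

  # out-of-range values evaluate at the training boundary
  v3 <- exprValues(X)
  pg <- ms@edges$parent[1]
  hi <- max(v3[, pg])
  v3[1, pg] <- hi + 50
  tr3 <- transferEcv(ms, v3)
  eid <- paste0(ms@edges$parent[1], "->", ms@edges$child[1])
  m <- ms@models[[ms@edges$child[1]]]
  expect_equal(unname(ecvValues(tr3$ecv)[1, eid]),
               componentValue(m, ms@edges$k[1], hi))

  # no computable edge at all
  lone <- matrix(rnorm(10), 10, 1, dimnames = list(paste0("p", 1:10), "zz"))
  expect_error(transferEcv(ms, lone), "empty-transfer")
})

test_that("edge-wise Welch tests match an independent oracle and guard ties", {
  set.seed(43)
  vals <- matrix(rnorm(40), 8, 5)
  vals[1:4, 1] <- vals[1:4, 1] + 3  # one clearly shifted edge
  E <- manualEcvMatrix(vals, parent = paste0("p", 1:5),
                       child = paste0("c", 1:5))
  res <- ecvEdgeTests(E, S = 1:4, T = 5:8)

  # oracle: Welch statistic and Welch-Satterthwaite p computed from formulas
  for (v in 1:5) {
    x <- vals[1:4, v]
    y <- vals[5:8, v]
    se2 <- var(x) / 4 + var(y) / 4
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
    expect_equal(res$t[v], tstat, tolerance = 1e-12)
    expect_equal(res$p[v], 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  }
  # oracle: BH step-up computed by hand on the sorted p-values
  m <- 5
  o <- order(res$p)
  qHand <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, res$p[o[i]] * m / i)
    qHand[o[i]] <- prev
  }
  expect_equal(res$q, qHand, tolerance = 1e-12)

  # identical groups: p = 1 territory after adjustment
  valsEq <- matrix(rep(c(1, 2, 3, 4), 5), 8, 5, byrow = FALSE)
  valsEq[5:8, ] <- valsEq[1:4, ]
  Eeq <- manualEcvMatrix(valsEq, parent = paste0("p", 1:5),
                         child = paste0("c", 1:5))
  resEq <- ecvEdgeTests(Eeq, 1:4, 5:8)
  expect_true(all(resEq$p == 1))
  expect_true(all(resEq$q == 1))

  # zero within-group variance with different means: p -> 0, no error
  valsC <- matrix(c(rep(1, 4), rep(2, 4)), 8, 1)
  Ec <- manualEcvMatrix(valsC, parent = "p", child = "c")
  resC <- ecvEdgeTests(Ec, 1:4, 5:8)
  expect_equal(resC$p, 0)
  expect_error(ecvEdgeTests(Ec, 1, 2:8), "insufficient replicates")
})

test_that("planted differential edges dominate and concentrate", {
  gt <- makeGroundTruth(seed = 5)
  X <- simulateExpression(gt, seed = 6)
  ms <- fitAllModels(exprValues(X), groundTruthNetwork(gt))
  E <- computeEcvMatrix(ms, X)
  si <- sampleInfo(X)
  S <- rownames(si)[si$condition == "treated"]
  Tc <- rownames(si)[si$condition == "control"]
  d <- deltaEcv(E, S, Tc)
  pk <- paste0(gt@perturbed$parent, "->", gt@perturbed$child)
  expect_true(all(d[pk] > 1.0))
  expect_true(all(d[setdiff(names(d), pk)] < 1.0))
  # delta-ECv of unperturbed edges concentrates near zero relative to the
  # per-gene log2 fold changes of the same simulation
  lfc <- degTest(X, S, Tc)$log2FC
  expect_lt(sd(d[setdiff(names(d), pk)]), sd(abs(lfc)))
})

test_that("ECv matrices round-trip through TSV", {
  gt <- makeGroundTruth(p = 8, nPerturbed = 2, seed = 51)
  X <- simulateExpression(gt, seed = 52)
  ms <- fitAllModels(exprValues(X), groundTruthNetwork(gt))
  E <- computeEcvMatrix(ms, X)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEcvMatrix(E, path)
  E2 <- readEcvMatrix(path)
  expect_identical(ecvValues(E2), ecvValues(E))
  expect_identical(E2@edges, E@edges)
})
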