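test_that("a parentless child is fitted as mean and variance", {
  X <- cbind(z = c(1, 2, 3))
  rownames(X) <- paste0("s", 1:3)
  m <- fitLocalModel(X, "z")
  expect_equal(m@constant, 2.0)
  expect_equal(m@sigma2, 2 / 3)
  expect_equal(predictLocalModel(m), 2.0)
})

test_that("bad inputs raise the documented errors", {
  X <- linearPairData(50)
  expect_error(fitLocalModel(X, "nope"), "unknown gene")
  expect_error(fitLocalModel(X, "b", c("a", "a", "a", "a")), "maxParents")
  X1 <- X[1, , drop = FALSE]
  expect_error(fitLocalModel(X1, "b", "a"), "insufficient data")
})

test_that("noise-free linear data are recovered essentially exactly", {
  set.seed(4)
  x <- runif(100)
  X <- cbind(a = x, b = 2 * x)
  rownames(X) <- paste0("s", seq_along(x))
  m <- fitLocalModel(X, "b", "a")
  expect_lt(sqrt(mean((componentValue(m, 1, x) - 2 * x)^2)), 1e-6)
  expect_lt(m@sigma2, 1e-10)
  expect_equal(componentValue(m, 1, 0.5), 1.0, tolerance = 1e-6)
  # component evaluation clamps outside the training range
  expect_equal(componentValue(m, 1, max(x) + 5), componentValue(m, 1, max(x)))
  expect_error(componentValue(m, 2, 0.5), "index error")
})

test_that("an additive nonlinear signal is recovered under noise", {
  set.seed(3)
  n <- 300
  x1 <- runif(n, -1.5, 1.5)
  x2 <- runif(n, -1.5, 1.5)
  ytrue <- sin(3 * x1) + x2^2
  X <- cbind(x1 = x1, x2 = x2, y = ytrue + rnorm(n, 0, 0.1))
  rownames(X) <- paste0("s", seq_len(n))
  m <- fitLocalModel(X, "y", c("x1", "x2"))
  pred <- predictLocalModel(m, cbind(x1, x2))
  expect_lte(sqrt(mean((pred - ytrue)^2)), 0.15)
})

test_that("refitting identical data reproduces identical parameters", {
  X <- linearPairData(120, seed = 9)
  m1 <- fitLocalModel(X, "b", "a")
  m2 <- fitLocalModel(X, "b", "a")
  expect_identical(m1@gamma, m2@gamma)
  expect_identical(m1@sigma2, m2@sigma2)
  expect_equal(localLogScore(X, "b", "a"), localLogScore(X, "b", "a"))
})

test_that("the score prefers true parents and penalizes irrelevant ones", {
  set.seed(5)
  n <- 200
  a <- rnorm(n)
  z <- rnorm(n)
  y <- 2 * a + rnorm(n, 0, 0.3)
  X <- cbind(a = a, z = z, y = y)
  rownames(X) <- paste0("s", seq_len(n))
  expect_gt(localLogScore(X, "y", "a"), localLogScore(X, "y", "z"))
  expect_gt(localLogScore(X, "y", "a"), localLogScore(X, "y", c("a", "z")))
  expect_gt(localLogScore(X, "y", "a"), localLogScore(X, "y"))
})

test_that("the true parent set wins among small candidate sets", {
  # spec-style consistency: best subset of size <= 2 from a 4-gene pool
  good <- 0
  for (r in 1:50) {
    set.seed(1000 + r)
    n <- 200
    a <- rnorm(n)
    b <- rnorm(n)
    d <- rnorm(n)
    y <- 1.2 * a - 0.9 * b + rnorm(n, 0, 0.3)
    X <- cbind(a = a, b = b, d = d, y = y)
    rownames(X) <- paste0("s", seq_len(n))
    cands <- list(character(), "a", "b", "d",
                  c("a", "b"), c("a", "d"), c("b", "d"))
    scores <- vapply(cands, function(pa) localLogScore(X, "y", pa),
                     numeric(1))
    if (identical(cands[[which.max(scores)]], c("a", "b"))) good <- good + 1
  }
  expect_gte(good, 45)
})

test_that("residual variance decreases as true parents are added (noise-free)", {
  set.seed(6)
  n <- 150
  a <- runif(n, -1, 1)
  b <- runif(n, -1, 1)
  y <- a + 0.5 * b^2
  X <- cbind(a = a, b = b, y = y)
  rownames(X) <- paste0("s", seq_len(n))
  s0 <- fitLocalModel(X, "y")@sigma2
  s1 <- fitLocalModel(X, "y", "a")@sigma2
  s2 <- fitLocalModel(X, "y", c("a", "b"))@sigma2
  expect_lte(s1, s0)
  expect_lte(s2, s1)
})

test_that("fitAllModels covers every node and respects structure", {
  X <- linearPairData(100, seed = 7)
  empty <- basalNetwork(colnames(X))
  msEmpty <- fitAllModels(X, empty)
  expect_length(msEmpty@models, 2L)
  expect_true(all(vapply(msEmpty@models,
                         function(m) length(m@parents) == 0L, logical(1))))

  set.seed(8)
  a <- rnorm(80)
  b <- a + rnorm(80, 0, 0.2)
  cc <- -b + rnorm(80, 0, 0.2)
  X3 <- cbind(a = a, b = b, c = cc)
  rownames(X3) <- paste0("s", 1:80)
  chain <- basalNetwork(c("a", "b", "c"), parent = c("a", "b"),
                        child = c("b", "c"))
  ms <- fitAllModels(X3, chain)
  expect_identical(ms@models[["b"]]@parents, "a")
  expect_identical(ms@models[["c"]]@parents, "b")
  expect_identical(ms@models[["a"]]@parents, character())
  ms2 <- fitAllModels(X3, chain)
  expect_identical(ms@models[["b"]]@gamma, ms2@models[["b"]]@gamma)
  expect_error(fitAllModels(X3[, 1:2], chain), "absent")
})

test_that("ModelSet JSON round trip reproduces ECv bit-identically", {
  gt <- makeGroundTruth(p = 8, nPerturbed = 2, seed = 21)
  X <- simulateExpression(gt, seed = 22)
  ms <- fitAllModels(exprValues(X), groundTruthNetwork(gt))
  path <- withr::local_tempfile(fileext = ".json")
  writeModelSet(ms, path)
  ms2 <- readModelSet(path)
  expect_identical(ms2@edges, ms@edges)
  E1 <- ecvValues(computeEcvMatrix(ms, X))
  E2 <- ecvValues(computeEcvMatrix(ms2, X))
  expect_identical(E1, E2)
})
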