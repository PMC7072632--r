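test_that("random DAGs are acyclic, seeded and respect parameters", {
  expect_equal(nrow(networkEdges(randomDag(1, seed = 1))), 0L)
  expect_equal(nrow(networkEdges(randomDag(10, edgeProb = 0, seed = 1))), 0L)
  d1 <- randomDag(12, edgeProb = 0.4, seed = 9)
  d2 <- randomDag(12, edgeProb = 0.4, seed = 9)
  expect_identical(networkEdges(d1), networkEdges(d2))
  e <- networkEdges(d1)
  g <- igraph::graph_from_data_frame(e[, c("parent", "child")],
                                     directed = TRUE)
  expect_true(igraph::is_dag(g))
  expect_true(all(table(e$child) <= 3))
})

test_that("ground truths validate their own invariants", {
  gt <- makeGroundTruth(p = 10, nPerturbed = 3, seed = 71)
  expect_true(validObject(gt))
  expect_equal(nrow(gt@perturbed), 3L)
  expect_true(all(gt@sigma > 0))
  g <- igraph::graph_from_data_frame(gt@edges[, c("parent", "child")],
                                     directed = TRUE)
  expect_true(igraph::is_dag(g))
  expect_error(makeGroundTruth(p = 6, nPerturbed = 3), "exceed")
})

test_that("children are exactly reproducible when noise vanishes", {
  gt <- makeGroundTruth(p = 9, nPerturbed = 2, sigma = 1e-12, seed = 72)
  X <- simulateExpression(gt, seed = 73, lineSd = 0)
  v <- exprValues(X)
  kids <- unique(gt@edges$child)
  for (ch in kids) {
    idx <- which(gt@edges$child == ch)
    recon <- gt@baseline[ch]
    for (i in idx)
      recon <- recon + trueComponent(gt, gt@edges$parent[i], ch,
                                     v[, gt@edges$parent[i]])
    expect_equal(unname(v[, ch]), unname(recon), tolerance = 1e-6)
  }
})

test_that("the planted component shift equals the nominal magnitude", {
  gt <- makeGroundTruth(p = 8, nPerturbed = 2, shift = 2, seed = 74)
  # Monte-Carlo over many replicates: the true component of a perturbed
  # edge differs between conditions by the shift (unit-slope transmission)
  X <- simulateExpression(gt, nPerCell = 500, seed = 75)
  v <- exprValues(X)
  si <- sampleInfo(X)
  for (i in seq_len(nrow(gt@perturbed))) {
    pg <- gt@perturbed$parent[i]
    ch <- gt@perturbed$child[i]
    compTreated <- mean(trueComponent(gt, pg, ch,
                                      v[si$condition == "treated", pg]))
    compControl <- mean(trueComponent(gt, pg, ch,
                                      v[si$condition == "control", pg]))
    expect_equal(compTreated - compControl, 2, tolerance = 0.1)
  }
  # unperturbed core edges are condition-balanced in expectation
  core <- gt@edges[!(paste(gt@edges$parent, gt@edges$child) %in%
                       paste(gt@perturbed$parent, gt@perturbed$child)), ]
  if (nrow(core)) {
    i <- 1
    dd <- mean(trueComponent(gt, core$parent[i], core$child[i],
                             v[si$condition == "treated", core$parent[i]])) -
      mean(trueComponent(gt, core$parent[i], core$child[i],
                         v[si$condition == "control", core$parent[i]]))
    expect_lt(abs(dd), 0.2)
  }
})

test_that("the simulated design matches the requested layout", {
  gt <- makeGroundTruth(p = 8, nPerturbed = 2, seed = 76)
  X <- simulateExpression(gt, seed = 77)
  si <- sampleInfo(X)
  expect_equal(nrow(exprValues(X)), 18L)
  expect_equal(as.vector(table(si$condition)), c(9L, 9L))
  expect_equal(as.vector(table(si$line)), c(6L, 6L, 6L))
  X2 <- simulateExpression(gt, seed = 77)
  expect_identical(exprValues(X), exprValues(X2))
})

test_that("survival simulation honors censoring and the hazard ratio", {
  g <- factor(rep(1:2, each = 5000))
  recNoCens <- simulateSurvival(g, censorRate = 0, seed = 81)
  expect_true(all(recNoCens$event == 1L))

  rec <- simulateSurvival(g, baselineHazard = 0.001, hazardRatio = 2,
                          censorRate = 0.3, seed = 82)
  byG <- split(rec, rec$group)
  rate <- vapply(byG, function(d) sum(d$event) / sum(d$time), numeric(1))
  expect_equal(unname(rate[2] / rate[1]), 2, tolerance = 0.1)
  # censoring calibration in the reference group
  expect_equal(mean(byG[[1]]$event == 0L), 0.3, tolerance = 0.05)
  expect_error(simulateSurvival(g, hazardRatio = 0), "hazardRatio")
})
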