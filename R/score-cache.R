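## Internal machinery shared by local-model fitting and structure search.
##
## All local scores for one data matrix are computed against a single cache
## holding, per gene, the spline basis built from that gene's observed range
## and its n-by-M design matrix. Gram blocks (crossproducts of per-gene
## design matrices) and child projections are memoized on demand, as is the
## best score per (child, parent set). This makes the iterated-subnetwork
## estimator cheap: once a parent set has been scored anywhere, every later
## subnetwork estimation reuses it.

## Second-order divided-difference penalty at the Greville abscissae of the
## clamped uniform basis. Divided (not plain) differences matter: the
## Greville points are unevenly spaced near clamped boundaries, and only
## the divided form leaves linear coefficient sequences exactly
## penalty-free, so linear signals are reproduced exactly at any smoothing
## weight. The abscissae pattern depends only on M (ranges rescale it), so
## one matrix serves every gene.
.smoothPenalty <- function(M) {
  knots01 <- c(rep(0, 3), seq(0, 1, length.out = M - 2L), rep(1, 3))
  xi <- vapply(seq_len(M), function(l) mean(knots01[(l + 1L):(l + 3L)]),
               numeric(1))
  D <- matrix(0, M - 2L, M)
  for (i in seq_len(M - 2L)) {
    l <- i + 1L
    a <- 1 / (xi[l] - xi[l - 1L])
    b <- 1 / (xi[l + 1L] - xi[l])
    D[i, (l - 1L):(l + 1L)] <- 2 / (xi[l + 1L] - xi[l - 1L]) *
      c(a, -(a + b), b)
  }
  D <- D * mean(diff(xi))^2  # interior rows ~ (1, -2, 1), boundary corrected
  crossprod(D)
}

.asExprMatrix <- function(X) {
  v <- exprValues(X)
  if (!is.numeric(v)) stop("expression values must be numeric")
  if (is.null(colnames(v))) stop("expression matrix must have gene names")
  v
}

.scoreCache <- function(X, cfg = scoreConfig()) {
  v <- .asExprMatrix(X)
  n <- nrow(v)
  if (n < 2L) stop("insufficient data: need at least 2 samples")
  p <- ncol(v)
  M <- cfg@M
  bases <- vector("list", p)
  Bmats <- vector("list", p)
  for (j in seq_len(p)) {
    bases[[j]] <- buildBasis(v[, j], M)
    Bmats[[j]] <- evaluateBasis(bases[[j]], v[, j])
  }
  K <- .smoothPenalty(M)
  eps <- cfg@ridgeEps
  pen <- lapply(cfg@lambdaGrid, function(lam) {
    A <- lam * K + diag(eps, M)
    list(A = A, ldA = as.numeric(determinant(A)$modulus))
  })
  e <- new.env(parent = emptyenv())
  e$X <- v
  e$n <- n
  e$p <- p
  e$genes <- colnames(v)
  e$cfg <- cfg
  e$bases <- bases
  e$Bmats <- Bmats
  e$yy <- colSums(v^2)
  e$ysum <- colSums(v)
  e$pen <- pen
  e$ld0 <- log(eps)
  e$eps <- eps
  e$gram <- new.env(parent = emptyenv())
  e$bty <- new.env(parent = emptyenv())
  e$memo <- new.env(parent = emptyenv())
  e
}

.gramBlock <- function(cache, j, k) {
  key <- if (j <= k) paste0(j, ":", k) else paste0(k, ":", j)
  g <- cache$gram[[key]]
  if (is.null(g)) {
    g <- crossprod(cache$Bmats[[min(j, k)]], cache$Bmats[[max(j, k)]])
    cache$gram[[key]] <- g
  }
  if (j <= k) g else t(g)
}

.btyVec <- function(cache, j, child) {
  key <- paste0(j, ":", child)
  b <- cache$bty[[key]]
  if (is.null(b)) {
    b <- as.vector(crossprod(cache$Bmats[[j]], cache$X[, child]))
    cache$bty[[key]] <- b
  }
  b
}

## Penalized marginal likelihood of child | parents, maximized over the
## lambda grid. Returns list(score, lambdaIdx). Prior on the stacked
## coefficient vector: gamma ~ N(0, sigma2 * A^-1) with A the block-diagonal
## second-difference penalty (lambda * D'D + eps I per parent); the noise
## variance is profiled out analytically, so the score is closed form.
.scoreRaw <- function(cache, child, parents) {
  n <- cache$n
  yy <- cache$yy[child]
  q <- length(parents)
  if (q == 0L) {
    s <- cache$ysum[child]
    quad <- yy - s * s / (n + cache$eps)
    quad <- max(quad, 1e-300)
    sc <- -n / 2 * (log(2 * pi * quad / n) + 1) -
      0.5 * (log(n + cache$eps) - cache$ld0)
    return(list(score = sc, lambdaIdx = NA_integer_))
  }
  M <- cache$cfg@M
  d <- q * M
  BtB <- matrix(0, d, d)
  Bty <- numeric(d)
  for (a in seq_len(q)) {
    ra <- ((a - 1L) * M + 1L):(a * M)
    Bty[ra] <- .btyVec(cache, parents[a], child)
    for (b in a:q) {
      rb <- ((b - 1L) * M + 1L):(b * M)
      g <- .gramBlock(cache, parents[a], parents[b])
      BtB[ra, rb] <- g
      if (b > a) BtB[rb, ra] <- t(g)
    }
  }
  best <- -Inf
  bestIdx <- 1L
  for (l in seq_along(cache$pen)) {
    H <- BtB
    A <- cache$pen[[l]]$A
    for (a in seq_len(q)) {
      ra <- ((a - 1L) * M + 1L):(a * M)
      H[ra, ra] <- H[ra, ra] + A
    }
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) next
    g <- backsolve(ch, forwardsolve(t(ch), Bty))
    quad <- max(yy - sum(Bty * g), 1e-300)
    ldH <- 2 * sum(log(diag(ch)))
    sc <- -n / 2 * (log(2 * pi * quad / n) + 1) -
      0.5 * (ldH - q * cache$pen[[l]]$ldA)
    if (sc > best) {
      best <- sc
      bestIdx <- l
    }
  }
  list(score = best, lambdaIdx = bestIdx)
}

.cachedScore <- function(cache, child, parents) {
  key <- if (length(parents))
    paste0(child, "|", paste(sort(parents), collapse = ","))
  else paste0(child, "|")
  s <- cache$memo[[key]]
  if (is.null(s)) {
    s <- .scoreRaw(cache, child, parents)$score
    cache$memo[[key]] <- s
  }
  s
}

## Penalized least-squares coefficients at the score-optimal lambda.
.fitRaw <- function(cache, child, parents) {
  q <- length(parents)
  n <- cache$n
  y <- cache$X[, child]
  if (q == 0L) {
    mu <- mean(y)
    return(list(gamma = list(), sigma2 = mean((y - mu)^2), constant = mu,
                lambda = NA_real_))
  }
  raw <- .scoreRaw(cache, child, parents)
  l <- raw$lambdaIdx
  M <- cache$cfg@M
  d <- q * M
  BtB <- matrix(0, d, d)
  Bty <- numeric(d)
  for (a in seq_len(q)) {
    ra <- ((a - 1L) * M + 1L):(a * M)
    Bty[ra] <- .btyVec(cache, parents[a], child)
    for (b in a:q) {
      rb <- ((b - 1L) * M + 1L):(b * M)
      g <- .gramBlock(cache, parents[a], parents[b])
      BtB[ra, rb] <- g
      if (b > a) BtB[rb, ra] <- t(g)
    }
  }
  H <- BtB
  A <- cache$pen[[l]]$A
  for (a in seq_len(q)) {
    ra <- ((a - 1L) * M + 1L):(a * M)
    H[ra, ra] <- H[ra, ra] + A
  }
  ch <- chol(H)
  g <- backsolve(ch, forwardsolve(t(ch), Bty))
  pred <- numeric(n)
  gamma <- vector("list", q)
  for (a in seq_len(q)) {
    ra <- ((a - 1L) * M + 1L):(a * M)
    gamma[[a]] <- g[ra]
    pred <- pred + cache$Bmats[[parents[a]]] %*% g[ra]
  }
  list(gamma = gamma, sigma2 = mean((y - pred)^2), constant = 0,
       lambda = cache$cfg@lambdaGrid[l])
}

.geneIndex <- function(cache, genes) {
  idx <- match(genes, cache$genes)
  if (anyNA(idx))
    stop("unknown gene(s): ", paste(genes[is.na(idx)], collapse = ", "))
  idx
}
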