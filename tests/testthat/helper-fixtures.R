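# Shared in-code fixtures; everything is generated from explicit seeds.

# samples-by-genes matrix with a single strong linear edge a -> b
linearPairData <- function(n = 200, slope = 2, noise = 0.3, seed = 1) {
  set.seed(seed)
  a <- stats::rnorm(n)
  b <- slope * a + stats::rnorm(n, 0, noise)
  m <- cbind(a = a, b = b)
  rownames(m) <- paste0("s", seq_len(n))
  m
}

# two independent standard normal genes
independentPairData <- function(n = 200, seed = 1) {
  set.seed(seed)
  m <- cbind(a = stats::rnorm(n), b = stats::rnorm(n))
  rownames(m) <- paste0("s", seq_len(n))
  m
}

# a small EcvMatrix built directly from values (for arithmetic tests)
manualEcvMatrix <- function(values, parent, child) {
  colnames(values) <- paste0(parent, "->", child)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  new("EcvMatrix", values = values,
      edges = data.frame(parent = parent, child = child,
                         stringsAsFactors = FALSE),
      provenance = "test fixture")
}

# per-line treated-vs-control groups from simulated sample annotations
lineGroups <- function(X) {
  si <- sampleInfo(X)
  lns <- sort(unique(si$line))
  stats::setNames(lapply(lns, function(l) list(
    S = rownames(si)[si$condition == "treated" & si$line == l],
    T = rownames(si)[si$condition == "control" & si$line == l])), lns)
}
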