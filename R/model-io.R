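## ModelSet serialization. Doubles are written as 17-significant-digit
## decimal strings, which round-trips IEEE doubles exactly, so ECv matrices
## recomputed from a reloaded ModelSet are bit-identical.

.numOut <- function(x) sprintf("%.17g", x)
.numIn <- function(x) as.numeric(x)

#' Write a ModelSet to a self-contained JSON document
#'
#' Stores, per child: the parent list, per-parent knot vectors and training
#' ranges, coefficient vectors, residual variance and training size. Numeric
#' values are serialized at full IEEE precision so that a reloaded set
#' reproduces ECv values bit-identically.
#'
#' @param models a [ModelSet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readModelSet()]
#' @export
writeModelSet <- function(models, path) {
  stopifnot(is(models, "ModelSet"))
  doc <- list(
    format = "ecvnet-modelset",
    version = 1L,
    genes = models@genes,
    edges = list(parent = models@edges$parent, child = models@edges$child,
                 k = models@edges$k),
    trainStats = list(gene = models@trainStats$gene,
                      mean = .numOut(models@trainStats$mean),
                      sd = .numOut(models@trainStats$sd)),
    models = lapply(models@models, function(m) {
      list(
        child = m@child,
        parents = m@parents,
        M = if (length(m@bases)) m@bases[[1]]@M else NA_integer_,
        knots = lapply(m@bases, function(b) .numOut(b@knots)),
        supportLo = .numOut(vapply(m@bases, slot, numeric(1), "supportLo")),
        supportHi = .numOut(vapply(m@bases, slot, numeric(1), "supportHi")),
        gamma = lapply(m@gamma, .numOut),
        sigma2 = .numOut(m@sigma2),
        constant = .numOut(m@constant),
        nTrain = m@nTrain
      )
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

#' Read a ModelSet written by [writeModelSet()]
#'
#' @param path path to a ModelSet JSON document.
#' @return A [ModelSet-class].
#' @export
readModelSet <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "ecvnet-modelset"))
    stop("not an ecvnet ModelSet document: ", path)
  chr <- function(x) as.character(unlist(x))
  num <- function(x) .numIn(unlist(x))
  models <- lapply(doc$models, function(m) {
    parents <- chr(m$parents)
    q <- length(parents)
    lo <- num(m$supportLo)
    hi <- num(m$supportHi)
    bases <- vector("list", q)
    gamma <- vector("list", q)
    for (k in seq_len(q)) {
      bases[[k]] <- new("SplineBasis", degree = 3L, M = as.integer(m$M),
                        knots = num(m$knots[[k]]), supportLo = lo[k],
                        supportHi = hi[k])
      gamma[[k]] <- num(m$gamma[[k]])
    }
    new("LocalModel", child = chr(m$child), parents = parents,
        bases = bases, gamma = gamma, sigma2 = num(m$sigma2),
        constant = num(m$constant), nTrain = as.integer(m$nTrain))
  })
  names(models) <- vapply(models, slot, character(1), "child")
  edges <- data.frame(parent = chr(doc$edges$parent),
                      child = chr(doc$edges$child),
                      k = as.integer(unlist(doc$edges$k)),
                      stringsAsFactors = FALSE)
  ts <- data.frame(gene = chr(doc$trainStats$gene),
                   mean = num(doc$trainStats$mean),
                   sd = num(doc$trainStats$sd), stringsAsFactors = FALSE)
  new("ModelSet", models = models, genes = chr(doc$genes), edges = edges,
      trainStats = ts)
}
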