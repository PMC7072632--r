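## Differential subnetwork assembly and topology summaries.

.subgraphIgraph <- function(net) {
  e <- networkEdges(net)
  nodes <- networkGenes(net)
  igraph::graph_from_data_frame(e[, c("parent", "child"), drop = FALSE],
                                directed = TRUE,
                                vertices = data.frame(name = nodes))
}

#' Assemble the differential subnetwork from extracted edges
#'
#' The node set is the endpoints of the extracted (differential) edges; the
#' edge set is the extracted edges plus every basal-network edge whose both
#' endpoints lie in that node set — the basal-network induced subgraph on
#' the extracted genes. Edges are tagged \code{delta_extracted} or
#' \code{basal_fill}; per-group delta-ECv columns present in
#' \code{extracted} are carried along.
#'
#' @param basal a [BasalNetwork-class].
#' @param extracted data.frame of extracted edges (columns \code{parent},
#'   \code{child}, optionally per-group delta-ECv annotations); must be a
#'   subset of the basal edges.
#' @return A [Subnetwork-class].
#' @export
buildSubnetwork <- function(basal, extracted) {
  stopifnot(is(basal, "BasalNetwork"))
  bk <- paste(basal@edges$parent, basal@edges$child, sep = "\r")
  ek <- paste(extracted$parent, extracted$child, sep = "\r")
  if (!all(ek %in% bk))
    stop("consistency error: extracted edges must be basal-network edges")
  nodes <- sort(unique(c(extracted$parent, extracted$child)))
  fill <- basal@edges[basal@edges$parent %in% nodes &
                        basal@edges$child %in% nodes, , drop = FALSE]
  fill <- fill[!(paste(fill$parent, fill$child, sep = "\r") %in% ek), ,
               drop = FALSE]
  annCols <- setdiff(names(extracted), c("parent", "child"))
  edges <- data.frame(parent = c(extracted$parent, fill$parent),
                      child = c(extracted$child, fill$child),
                      origin = c(rep("delta_extracted", nrow(extracted)),
                                 rep("basal_fill", nrow(fill))),
                      stringsAsFactors = FALSE)
  for (a in annCols)
    edges[[a]] <- c(extracted[[a]], rep(NA_real_, nrow(fill)))
  ord <- order(edges$origin != "delta_extracted", edges$parent, edges$child)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  new("Subnetwork", nodes = nodes, edges = edges)
}

#' Hub genes by total degree
#'
#' Nodes ranked by total (in + out) degree, descending, with deterministic
#' lexicographic ordering among equal degrees. Returns the top
#' \code{ceiling(fraction * n)} nodes, extended to include every node tied
#' with the cutoff degree.
#'
#' @param net a [Subnetwork-class] or [BasalNetwork-class].
#' @param fraction fraction of nodes to return, in (0, 1] (default 0.05).
#' @return data.frame with columns \code{gene} and \code{degree}, ranked.
#' @export
hubNodes <- function(net, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  nodes <- networkGenes(net)
  if (!length(nodes))
    return(data.frame(gene = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  e <- networkEdges(net)
  deg <- table(factor(c(e$parent, e$child), levels = nodes))
  ord <- order(-as.integer(deg), names(deg))
  deg <- as.integer(deg)[ord]
  genes <- nodes[ord]
  nTop <- ceiling(fraction * length(genes))
  cutoff <- deg[nTop]
  keep <- seq_len(max(nTop, sum(deg >= cutoff)))
  data.frame(gene = genes[keep], degree = deg[keep], stringsAsFactors = FALSE)
}

#' Weakly connected components of a network
#'
#' @param net a [Subnetwork-class] or [BasalNetwork-class].
#' @return list of character vectors (node sets), largest first; ties by
#'   lexicographically smallest member.
#' @export
networkComponents <- function(net) {
  nodes <- networkGenes(net)
  if (!length(nodes)) return(list())
  g <- .subgraphIgraph(net)
  comp <- igraph::components(g, mode = "weak")
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, sort)
  sets[order(-vapply(sets, length, integer(1)),
             vapply(sets, `[`, character(1), 1L))]
}

#' Write a subnetwork edge table as TSV
#'
#' Columns: parent, child, origin, plus any delta-ECv annotation columns.
#'
#' @param net a [Subnetwork-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSubnetworkTsv <- function(net, path) {
  stopifnot(is(net, "Subnetwork"))
  utils::write.table(net@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a subnetwork in GraphML format
#'
#' Nodes carry \code{degree} and \code{hub} attributes (hub = member of
#' [hubNodes()] at the given fraction); edges carry \code{origin} and any
#' delta-ECv annotation columns. Consumable by standard network viewers.
#'
#' @param net a [Subnetwork-class].
#' @param path output path.
#' @param hubFraction fraction used for the hub flag (default 0.05).
#' @return \code{path}, invisibly.
#' @export
writeSubnetworkGraphml <- function(net, path, hubFraction = 0.05) {
  stopifnot(is(net, "Subnetwork"))
  e <- net@edges
  deg <- table(factor(c(e$parent, e$child), levels = net@nodes))
  hubs <- hubNodes(net, hubFraction)$gene
  vattr <- data.frame(name = net@nodes,
                      degree = as.integer(deg[net@nodes]),
                      hub = net@nodes %in% hubs,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(e, directed = TRUE, vertices = vattr)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
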