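## Protein interaction networks and maximal clique centrality.
##
## STRING-format edge lists are loaded at a confidence threshold, maximal
## cliques enumerated (Bron-Kerbosch with pivoting, via igraph), and nodes
## ranked by Maximal Clique Centrality:
##   MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!
## with the 0! = 1 convention giving every isolated node a score of 1.

#' Read a STRING-format edge list
#'
#' Parses a TSV with columns `protein1`, `protein2`, `combined_score`
#' (STRING convention, scores 0-1000), keeps edges with score >= the
#' threshold, and returns a simple undirected igraph (duplicate and
#' reversed edges collapsed, self-loops dropped).
#'
#' @param path TSV path.
#' @param scoreThreshold minimum combined score (default 400, medium
#'   confidence).
#' @param nodes optional node subset; the graph is induced on it.
#' @return igraph object with edge attribute `score`.
#' @export
readStringEdges <- function(path, scoreThreshold = 400, nodes = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(tab)))
    stop("STRING edge list must have columns: ",
         paste(need, collapse = ", "))
  score <- suppressWarnings(as.numeric(tab$combined_score))
  bad <- which(is.na(score) | is.na(tab$protein1) | is.na(tab$protein2) |
                 tab$protein1 == "" | tab$protein2 == "")
  if (length(bad))
    stop("malformed STRING edge row at line ", bad[1] + 1L)
  keep <- score >= scoreThreshold
  g <- igraph::graph_from_data_frame(
    data.frame(from = tab$protein1[keep], to = tab$protein2[keep],
               score = score[keep]), directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  if (!is.null(nodes))
    g <- igraph::induced_subgraph(
      g, intersect(igraph::V(g)$name, nodes))
  g
}

#' Enumerate all maximal cliques
#'
#' Exhaustive maximal clique enumeration (Bron-Kerbosch with pivoting).
#' Isolated nodes form singleton maximal cliques.  Guarded by a node cap:
#' enumeration is exponential in the worst case.
#'
#' @param graph simple undirected igraph.
#' @param maxNodes refuse graphs larger than this (raise deliberately for
#'   bigger inputs).
#' @return list of character vectors of node names.
#' @export
maximalCliques <- function(graph, maxNodes = 5000L) {
  if (igraph::vcount(graph) > maxNodes)
    stop("graph has ", igraph::vcount(graph), " nodes; raise 'maxNodes' ",
         "to enumerate cliques on graphs this large")
  cl <- igraph::max_cliques(graph, min = 1)
  lapply(cl, function(v) igraph::V(graph)$name[as.integer(v)])
}

#' Maximal clique centrality scores
#'
#' `MCC(v) = sum_{maximal cliques C with v in C} (|C| - 1)!`.  Factorials
#' are exact doubles up to clique size 23; larger cliques error out rather
#' than overflow silently.
#'
#' @param graph simple undirected igraph (or a list of cliques from
#'   [maximalCliques()] plus `nodes`).
#' @param cliques optional precomputed maximal cliques.
#' @return named numeric vector of MCC scores, one per node.
#' @export
mccScores <- function(graph, cliques = NULL) {
  nodes <- igraph::V(graph)$name
  if (is.null(cliques)) cliques <- maximalCliques(graph)
  sizes <- lengths(cliques)
  if (any(sizes > 23))
    stop("clique of size ", max(sizes),
         " exceeds the exact-factorial range of double precision")
  scores <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(cliques))
    scores[cliques[[i]]] <- scores[cliques[[i]]] + factorial(sizes[i] - 1)
  scores
}

#' Extract the top-k hub set
#'
#' The k highest-MCC nodes.  Ties crossing the boundary are broken by
#' degree, then lexicographic node name, and flagged.
#'
#' @param scores named MCC vector from [mccScores()].
#' @param k hub count.
#' @param graph the scored graph (for degree tie-breaking); optional.
#' @return character vector of k node names, attribute `tied` TRUE when
#'   the boundary was tie-broken.
#' @export
topKHubs <- function(scores, k, graph = NULL) {
  if (k > length(scores))
    stop("k = ", k, " exceeds the node count ", length(scores))
  deg <- if (!is.null(graph))
    igraph::degree(graph)[names(scores)] else rep(0, length(scores))
  ord <- order(-scores, -deg, names(scores))
  sorted <- scores[ord]
  tied <- k < length(scores) && sorted[k] == sorted[k + 1]
  out <- names(sorted)[seq_len(k)]
  attr(out, "tied") <- tied
  out
}

#' Write a graph as a STRING-format edge list
#'
#' @param graph igraph with optional `score` edge attribute (defaults to
#'   999 when absent).
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeStringEdges <- function(graph, path) {
  e <- igraph::as_edgelist(graph)
  score <- igraph::edge_attr(graph, "score") %||% rep(999, nrow(e))
  .writeTSV(data.frame(protein1 = e[, 1], protein2 = e[, 2],
                       combined_score = score), path)
}
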