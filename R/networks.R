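#' Build a coevolution network from retained pairs
#'
#' Nodes are sites (labelled `protein:site`, or by residue label when
#' residue columns are present); undirected edges are the retained pairs,
#' with bootstrap support kept as an edge attribute. Self loops are removed
#' and duplicate pairs collapse to a single edge (highest support kept).
#'
#' @param pairs data.frame with columns `site_a`, `site_b` (and optionally
#'   `protein_a`, `protein_b`, `support`), or precomputed `node_a`,
#'   `node_b` labels. An empty data.frame yields an empty graph.
#' @return an [igraph::graph] object.
#' @export
buildNetwork <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  if (!"node_a" %in% names(pairs)) {
    lab <- function(prot, site) if (is.null(prot)) as.character(site)
      else paste0(prot, ":", site)
    pairs$node_a <- lab(pairs$protein_a, pairs$site_a)
    pairs$node_b <- lab(pairs$protein_b, pairs$site_b)
  }
  el <- data.frame(from = pairs$node_a, to = pairs$node_b)
  if (!is.null(pairs$support)) el$support <- pairs$support
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "max")
}

#' Degree centrality
#'
#' Number of edges at each node.
#'
#' @param net an undirected [igraph::graph].
#' @return named integer vector.
#' @export
degreeCentrality <- function(net) {
  d <- igraph::degree(net, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Closeness centrality (component-normalized)
#'
#' For a node in a connected component of size `n_c`,
#' `(n_c - 1) / sum(shortest-path lengths to its component peers)` with unit
#' edge lengths. Nodes in single-node components get 0 by convention.
#'
#' @param net an undirected [igraph::graph].
#' @param raw if `TRUE`, return the unnormalized reciprocal farness
#'   `1 / sum(d)` instead.
#' @return named numeric vector.
#' @export
closenessCentrality <- function(net, raw = FALSE) {
  n <- igraph::vcount(net)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  comp <- igraph::components(net)$membership
  D <- igraph::distances(net)
  out <- stats::setNames(numeric(n), igraph::V(net)$name)
  for (v in seq_len(n)) {
    peers <- which(comp == comp[v])
    peers <- peers[peers != v]
    if (length(peers) == 0L) { out[v] <- 0; next }
    farness <- sum(D[v, peers])
    out[v] <- if (raw) 1 / farness else length(peers) / farness
  }
  out
}

#' Betweenness centrality (unnormalized)
#'
#' For each node `v`, the sum over unordered node pairs `(s, t)` (both
#' different from `v`) of the fraction of shortest `s`-`t` paths passing
#' through `v`, with unit edge lengths.
#'
#' @param net an undirected [igraph::graph].
#' @return named numeric vector.
#' @export
betweennessCentrality <- function(net) {
  igraph::betweenness(net, directed = FALSE, normalized = FALSE)
}

#' Node centrality table
#'
#' @param net an undirected [igraph::graph].
#' @return data.frame: `node`, `degree`, `closeness` (component-normalized),
#'   `closeness_raw`, `betweenness`, `component`, sorted by node label.
#' @export
centralityTable <- function(net) {
  if (igraph::vcount(net) == 0L)
    return(data.frame(node = character(0), degree = integer(0),
                      closeness = numeric(0), closeness_raw = numeric(0),
                      betweenness = numeric(0), component = integer(0)))
  nodes <- igraph::V(net)$name
  tab <- data.frame(
    node = nodes,
    degree = degreeCentrality(net),
    closeness = closenessCentrality(net),
    closeness_raw = closenessCentrality(net, raw = TRUE),
    betweenness = betweennessCentrality(net),
    component = as.integer(igraph::components(net)$membership),
    row.names = NULL)
  tab[order(tab$node), , drop = FALSE]
}

#' Network edge list
#'
#' @param net an undirected [igraph::graph].
#' @return data.frame: `node_a`, `node_b`, `support` (NA when absent).
#' @export
edgeTable <- function(net) {
  if (igraph::ecount(net) == 0L)
    return(data.frame(node_a = character(0), node_b = character(0),
                      support = numeric(0)))
  el <- igraph::as_edgelist(net)
  sup <- if ("support" %in% igraph::edge_attr_names(net))
    igraph::E(net)$support else rep(NA_real_, nrow(el))
  out <- data.frame(node_a = pmin(el[, 1L], el[, 2L]),
                    node_b = pmax(el[, 1L], el[, 2L]), support = sup)
  out[order(out$node_a, out$node_b), , drop = FALSE]
}
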