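# Centrality measures on the simple undirected projection of an associative
# network. Definitions follow the common network-analysis conventions:
# degree centrality deg(v)/(n-1); closeness with reachable-set scaling on
# disconnected graphs; betweenness normalized by 2/((n-1)(n-2)) with each
# unordered pair counted once.

#' Project a network onto a simple undirected graph
#'
#' Parallel edges of different interaction types collapse to a single
#' undirected edge, self-loops are removed, and antiparallel directed edges
#' merge. Vertex identity (distinct gene/protein forms) is preserved:
#' vertices are named `symbol|kind` and carry `symbol` and `kind`
#' attributes.
#'
#' @param net an [assoc_network()], or an igraph graph (returned as a
#'   simplified undirected copy).
#' @return an undirected simple `igraph` graph.
#' @export
project_simple_undirected <- function(net) {
  g <- if (inherits(net, "igraph")) {
    igraph::as_undirected(net, mode = "collapse")
  } else {
    network_igraph(net)
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

as_simple_graph <- function(g) {
  if (!inherits(g, "igraph")) g <- project_simple_undirected(g)
  if (igraph::is_directed(g) || igraph::any_multiple(g) ||
      any(igraph::which_loop(g))) {
    g <- project_simple_undirected(g)
  }
  g
}

#' Degree centrality
#'
#' `DC(v) = deg(v) / (n - 1)` on the simple undirected projection.
#'
#' @param g an igraph graph or an [assoc_network()] (projected first).
#' @return named numeric vector in `[0, 1]`; errors when the graph has
#'   fewer than 2 vertices.
#' @export
degree_centrality <- function(g) {
  g <- as_simple_graph(g)
  n <- igraph::vcount(g)
  if (n < 2L) stop("degree centrality requires at least 2 vertices",
                   call. = FALSE)
  igraph::degree(g) / (n - 1)
}

#' Closeness centrality
#'
#' For vertex `v` with reachable set `R(v)` (including `v`):
#' `CC(v) = ((|R|-1) / sum of distances) * ((|R|-1) / (n-1))`, which on a
#' connected graph reduces to `(n-1) / sum of distances`. Isolated vertices
#' get 0 by convention.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(g) {
  g <- as_simple_graph(g)
  n <- igraph::vcount(g)
  if (n < 2L) stop("closeness centrality requires at least 2 vertices",
                   call. = FALSE)
  d <- igraph::distances(g)
  vapply(seq_len(n), function(i) {
    di <- d[i, ]
    reach <- is.finite(di)
    r <- sum(reach)                       # includes i itself
    if (r <= 1L) return(0)
    tot <- sum(di[reach])
    ((r - 1) / tot) * ((r - 1) / (n - 1))
  }, numeric(1L), USE.NAMES = FALSE) -> cc
  setNames(cc, igraph::V(g)$name)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths through each vertex, endpoints excluded,
#' each unordered pair counted once, normalized by `2 / ((n-1)(n-2))`.
#' Graphs with fewer than 3 vertices get an all-zero profile.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(g) {
  g <- as_simple_graph(g)
  n <- igraph::vcount(g)
  if (n < 3L) return(setNames(numeric(n), igraph::V(g)$name))
  raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  raw * 2 / ((n - 1) * (n - 2))
}

#' Per-symbol centrality profile of a network
#'
#' Computes degree, closeness and betweenness centrality on the simple
#' undirected projection (gene and protein vertices distinct), then
#' aggregates per gene symbol by taking the maximum over that symbol's
#' vertex forms. `mean3` is the arithmetic mean of the three aggregated
#' measures and is the score behind the centrality ranking criteria.
#'
#' @param net an [assoc_network()].
#' @return object of class `centrality_profile` (a data frame with columns
#'   `symbol`, `dc`, `cc`, `bc`, `mean3`, one row per symbol, sorted by
#'   symbol). Per-vertex values are kept in the `"vertex"` attribute.
#' @export
gene_centrality_profile <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  g <- project_simple_undirected(net)
  n <- igraph::vcount(g)
  if (n < 2L) {
    stop("centrality profile requires a network with at least 2 vertices",
         call. = FALSE)
  }
  dc <- degree_centrality(g)
  cc <- closeness_centrality(g)
  bc <- betweenness_centrality(g)
  sym <- igraph::V(g)$symbol
  per_vertex <- data.frame(vertex = igraph::V(g)$name, symbol = sym,
                           dc = unname(dc), cc = unname(cc),
                           bc = unname(bc), stringsAsFactors = FALSE)
  agg <- function(v) vapply(split(v, sym), max, numeric(1L))
  out <- data.frame(symbol = sort(unique(sym)), stringsAsFactors = FALSE)
  out$dc <- agg(unname(dc))[out$symbol]
  out$cc <- agg(unname(cc))[out$symbol]
  out$bc <- agg(unname(bc))[out$symbol]
  out$mean3 <- (out$dc + out$cc + out$bc) / 3
  rownames(out) <- NULL
  attr(out, "vertex") <- per_vertex
  class(out) <- c("centrality_profile", "data.frame")
  out
}
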