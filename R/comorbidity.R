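# Comorbidity network construction: the "complete" network of a disease
# pair is the intersection of the two single-disease networks (shared
# vertices and shared typed edges); its genetic regulatory subnetwork keeps
# only expression-regulation edge types.

#' Intersect two associative networks
#'
#' Vertices are matched by (symbol, kind); edges must agree on endpoints,
#' interaction type and direction to be retained. Shared vertices without
#' any shared edge are kept as isolated nodes, so that downstream ranking
#' criteria are defined for every shared gene.
#'
#' @param a,b [assoc_network()] objects.
#' @return an [assoc_network()]; the empty intersection is valid.
#' @export
intersect_networks <- function(a, b) {
  stopifnot(inherits(a, "assoc_network"), inherits(b, "assoc_network"))
  nodes <- merge(a$nodes, b$nodes, by = c("symbol", "kind"))
  keep <- edge_key(a$edges) %in% edge_key(b$edges)
  edges <- a$edges[keep, edge_columns, drop = FALSE]
  label <- paste(a$label, b$label, sep = " x ")
  assoc_network(nodes = nodes, edges = edges, label = label)
}

#' Extract the genetic regulatory subnetwork
#'
#' Keeps only edges whose interaction type is expression regulation
#' (see [regulatory_itypes()]) and only vertices incident to a retained
#' edge; edge direction is preserved.
#'
#' @param net an [assoc_network()].
#' @return an [assoc_network()].
#' @export
extract_regulatory_subnetwork <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  edges <- net$edges[net$edges$itype %in% regulatory_itypes(), edge_columns,
                     drop = FALSE]
  nodes <- unique(data.frame(
    symbol = c(edges$src_symbol, edges$tgt_symbol),
    kind = c(edges$src_kind, edges$tgt_kind), stringsAsFactors = FALSE))
  assoc_network(nodes = nodes, edges = edges,
                label = paste0(net$label, " (regulatory)"))
}

#' Connected components of a network
#'
#' Components of the undirected vertex reachability relation (edge types
#' and directions ignored), including isolated vertices.
#'
#' @param net an [assoc_network()].
#' @return list of character vectors of vertex ids (`symbol|kind`), sorted
#'   by decreasing component size; empty list for an empty network.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  if (nrow(net$nodes) == 0L) return(list())
  g <- network_igraph(net)
  comp <- igraph::components(g)
  grouped <- unname(split(names(comp$membership), comp$membership))
  grouped <- lapply(grouped, sort)
  grouped[order(-lengths(grouped), vapply(grouped, `[`, character(1L), 1L))]
}

# igraph view of a network: vertices named symbol|kind with symbol/kind
# attributes; one undirected edge per stored edge (multi-edges retained)
network_igraph <- function(net) {
  ids <- node_id(net$nodes$symbol, net$nodes$kind)
  vdf <- data.frame(name = ids, symbol = net$nodes$symbol,
                    kind = net$nodes$kind, stringsAsFactors = FALSE)
  edf <- data.frame(from = node_id(net$edges$src_symbol, net$edges$src_kind),
                    to = node_id(net$edges$tgt_symbol, net$edges$tgt_kind),
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Build the comorbidity bundle for a disease pair
#'
#' Intersects the two disease networks into the complete comorbidity
#' network, extracts its genetic regulatory subnetwork, and collects the
#' shared gene symbols (the ranking candidates).
#'
#' @param a,b single-disease [assoc_network()] objects.
#' @return object of class `comorbidity_bundle`: list with `complete`,
#'   `regulatory` (both [assoc_network()]) and `shared_genes` (character).
#' @export
build_comorbidity <- function(a, b) {
  complete <- intersect_networks(a, b)
  structure(list(
    complete = complete,
    regulatory = extract_regulatory_subnetwork(complete),
    shared_genes = network_symbols(complete, kind = "gene")
  ), class = "comorbidity_bundle")
}

#' @export
print.comorbidity_bundle <- function(x, ...) {
  cat("Comorbidity bundle\n")
  cat("  shared genes:", length(x$shared_genes), "\n")
  cat("  complete network:", nrow(x$complete$nodes), "nodes,",
      nrow(x$complete$edges), "edges\n")
  cat("  regulatory subnetwork:", nrow(x$regulatory$nodes), "nodes,",
      nrow(x$regulatory$edges), "edges\n")
  invisible(x)
}
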