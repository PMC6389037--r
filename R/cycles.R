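# Fundamental cycle basis of the simple undirected projection. A spanning
# forest is grown by breadth-first search from the lexicographically
# smallest vertex of each component (neighbors visited in lexicographic
# order, so the basis is deterministic); every non-forest edge closes
# exactly one cycle with the forest path between its endpoints. The basis
# spans the cycle space: its size is |E| - |V| + #components, and any
# simple cycle of the graph is a symmetric difference of basis cycles.

#' Fundamental cycle basis
#'
#' @param g an igraph graph or an [assoc_network()] (projected onto its
#'   simple undirected form first).
#' @return object of class `cycle_basis`: list with `cycles` (list of
#'   character vectors, each a closed walk written as its distinct vertex
#'   sequence), `symbol_of` (named map vertex name -> gene symbol),
#'   `n_vertices`, `n_edges`, `n_components`, `graph_ref`.
#' @export
fundamental_cycle_basis <- function(g) {
  label <- if (inherits(g, "assoc_network")) g$label else ""
  g <- as_simple_graph(g)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  sym <- igraph::vertex_attr(g, "symbol")
  if (is.null(sym)) sym <- nm
  symbol_of <- setNames(sym, nm)

  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  if (nrow(el) > 0L) {
    adj_from <- split(c(el[, 2L], el[, 1L]), c(el[, 1L], el[, 2L]))
    for (k in names(adj_from)) {
      i <- as.integer(k)
      adj[[i]] <- as.integer(adj_from[[k]])[order(nm[adj_from[[k]]])]
    }
  }

  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  tree_key <- character(0)
  n_components <- 0L
  for (root in order(nm)) {
    if (visited[root]) next
    n_components <- n_components + 1L
    visited[root] <- TRUE
    depth[root] <- 0L
    queue <- root
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (!visited[v]) {
          visited[v] <- TRUE
          parent[v] <- u
          depth[v] <- depth[u] + 1L
          tree_key <- c(tree_key,
                        paste(min(u, v), max(u, v), sep = "_"))
          queue <- c(queue, v)
        }
      }
    }
  }
  tree_key <- unique(tree_key)

  cycles <- list()
  if (nrow(el) > 0L) {
    keys <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]),
                  sep = "_")
    chords <- which(!keys %in% tree_key)
    # deterministic cycle order: chords sorted by endpoint names
    chords <- chords[order(nm[pmin(el[chords, 1L], el[chords, 2L])],
                           nm[pmax(el[chords, 1L], el[chords, 2L])])]
    for (e in chords) {
      u <- el[e, 1L]; v <- el[e, 2L]
      up_u <- integer(0); up_v <- integer(0)
      a <- u; b <- v
      while (depth[a] > depth[b]) { up_u <- c(up_u, a); a <- parent[a] }
      while (depth[b] > depth[a]) { up_v <- c(up_v, b); b <- parent[b] }
      while (a != b) {
        up_u <- c(up_u, a); a <- parent[a]
        up_v <- c(up_v, b); b <- parent[b]
      }
      cycles[[length(cycles) + 1L]] <- nm[c(up_u, a, rev(up_v))]
    }
  }

  structure(list(cycles = cycles, symbol_of = symbol_of,
                 n_vertices = n, n_edges = nrow(el),
                 n_components = n_components, graph_ref = label),
            class = "cycle_basis")
}

#' @export
print.cycle_basis <- function(x, ...) {
  cat("Fundamental cycle basis",
      if (nzchar(x$graph_ref)) paste0("of '", x$graph_ref, "'"), "\n")
  cat("  graph: ", x$n_vertices, " vertices, ", x$n_edges, " edges, ",
      x$n_components, " component(s)\n", sep = "")
  cat("  cycles:", length(x$cycles), "\n")
  if (length(x$cycles) > 0L) {
    cat("  cycle lengths:", paste(range(lengths(x$cycles)), collapse = "-"),
        "\n")
  }
  invisible(x)
}

#' Gene-subset statistics over a cycle basis
#'
#' Counts how many basis cycles contain at least one vertex whose gene
#' symbol belongs to the subset, how many consist exclusively of subset
#' symbols, and reports a maximum-length subset-only cycle. Gene and
#' protein forms of a subset symbol both count as members.
#'
#' @param basis a [fundamental_cycle_basis()].
#' @param subset character vector of gene symbols.
#' @return list with `n_total`, `n_containing`, `n_only`,
#'   `longest_only_cycle` (character vector of vertex names; empty when no
#'   subset-only cycle exists). Always `n_only <= n_containing <= n_total`.
#' @export
cycle_set_statistics <- function(basis, subset) {
  stopifnot(inherits(basis, "cycle_basis"))
  subset <- unique(as.character(subset))
  in_subset <- lapply(basis$cycles,
                      function(cy) basis$symbol_of[cy] %in% subset)
  containing <- vapply(in_subset, any, logical(1L))
  only <- vapply(in_subset, all, logical(1L)) & containing
  longest <- character(0)
  if (any(only)) {
    only_cycles <- basis$cycles[only]
    longest <- only_cycles[[which.max(lengths(only_cycles))]]
  }
  list(n_total = length(basis$cycles),
       n_containing = sum(containing),
       n_only = sum(only),
       longest_only_cycle = longest)
}
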