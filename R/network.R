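# Associative network container: typed multigraph over gene and protein
# vertices. Gene and protein forms of the same symbol are distinct vertices;
# symbol-level views are produced downstream (centrality aggregation), never
# in storage.

.node_kinds <- c("gene", "protein")

edge_columns <- c("src_symbol", "src_kind", "tgt_symbol", "tgt_kind",
                  "itype", "directed")

empty_edges <- function() {
  data.frame(src_symbol = character(), src_kind = character(),
             tgt_symbol = character(), tgt_kind = character(),
             itype = character(), directed = logical(),
             stringsAsFactors = FALSE)
}

node_id <- function(symbol, kind) paste(symbol, kind, sep = "|")

# canonical storage form: undirected edges keep their endpoints in
# lexicographic (symbol, kind) order so that duplicate detection and
# network intersection are order-insensitive
canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  src <- node_id(edges$src_symbol, edges$src_kind)
  tgt <- node_id(edges$tgt_symbol, edges$tgt_kind)
  swap <- !edges$directed & tgt < src
  if (any(swap)) {
    tmp_sym <- edges$src_symbol[swap]
    tmp_kind <- edges$src_kind[swap]
    edges$src_symbol[swap] <- edges$tgt_symbol[swap]
    edges$src_kind[swap] <- edges$tgt_kind[swap]
    edges$tgt_symbol[swap] <- tmp_sym
    edges$tgt_kind[swap] <- tmp_kind
  }
  edges
}

edge_key <- function(edges) {
  paste(edges$src_symbol, edges$src_kind, edges$tgt_symbol, edges$tgt_kind,
        edges$itype, edges$directed, sep = "\r")
}

#' Construct an associative network
#'
#' An associative network is a typed multigraph whose vertices are gene or
#' protein forms of gene symbols and whose edges carry an interaction type
#' from the registered vocabulary (see [interaction_types()]). Parallel edges
#' of different types are allowed; duplicate edges (same endpoints, type and
#' direction) are collapsed. Undirected edges are stored with endpoints in
#' canonical order. Self-loops are permitted and flagged in the `self_loop`
#' edge column.
#'
#' @param nodes data frame with columns `symbol`, `kind`
#'   (`"gene"`/`"protein"`); endpoints of `edges` are added automatically.
#' @param edges data frame with columns `src_symbol`, `src_kind`,
#'   `tgt_symbol`, `tgt_kind`, `itype`, `directed` (logical). `NULL` for an
#'   edgeless network.
#' @param label character scalar naming the network.
#' @return object of class `assoc_network`: list with elements `nodes`,
#'   `edges`, `label`.
#' @seealso [read_network()], [network_summary()], [intersect_networks()]
#' @export
assoc_network <- function(nodes = NULL, edges = NULL, label = "") {
  if (is.null(edges)) edges <- empty_edges()
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  missing_cols <- setdiff(edge_columns, names(edges))
  if (length(missing_cols) > 0L) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  edges <- edges[, edge_columns]
  check_itypes(edges$itype)
  edges$directed <- as.logical(edges$directed)
  if (anyNA(edges$directed)) stop("edge 'directed' flag must be logical",
                                  call. = FALSE)
  bad_kind <- setdiff(unique(c(edges$src_kind, edges$tgt_kind)), .node_kinds)
  if (length(bad_kind) > 0L) {
    stop("unknown node kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(edges$src_symbol)) || any(!nzchar(edges$tgt_symbol))) {
    stop("empty gene symbol in edge table", call. = FALSE)
  }

  endpoint_nodes <- unique(data.frame(
    symbol = c(edges$src_symbol, edges$tgt_symbol),
    kind = c(edges$src_kind, edges$tgt_kind),
    stringsAsFactors = FALSE))
  if (is.null(nodes)) {
    nodes <- endpoint_nodes
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    stopifnot(all(c("symbol", "kind") %in% names(nodes)))
    nodes <- nodes[, c("symbol", "kind")]
    bad_kind <- setdiff(unique(nodes$kind), .node_kinds)
    if (length(bad_kind) > 0L) {
      stop("unknown node kind(s): ", paste(bad_kind, collapse = ", "),
           call. = FALSE)
    }
    if (any(!nzchar(nodes$symbol))) stop("empty gene symbol in node table",
                                         call. = FALSE)
    nodes <- unique(rbind(nodes, endpoint_nodes))
  }
  nodes <- nodes[order(nodes$symbol, nodes$kind), , drop = FALSE]
  rownames(nodes) <- NULL

  edges <- canonicalize_edges(edges)
  edges <- edges[!duplicated(edge_key(edges)), , drop = FALSE]
  edges$self_loop <- edges$src_symbol == edges$tgt_symbol &
    edges$src_kind == edges$tgt_kind
  rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges, label = label),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  s <- network_summary(x)
  cat("Associative network", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat("  nodes:", s$n_nodes, paste0("(", s$n_genes, " genes, ",
                                    s$n_proteins, " proteins)"), "\n")
  cat("  edges:", s$n_edges, "\n")
  if (s$n_edges > 0L) {
    tt <- s$edges_by_type[s$edges_by_type > 0L]
    cat("  types:", paste(names(tt), tt, sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize an associative network
#'
#' Counts nodes by kind and edges by interaction type. Per-type counts sum
#' to the total edge count and gene + protein counts to the node count.
#'
#' @param net an [assoc_network()].
#' @return object of class `assoc_network_summary`: list with `label`,
#'   `n_nodes`, `n_genes`, `n_proteins`, `n_edges`, `edges_by_type`
#'   (named integer vector over the full vocabulary), `n_self_loops`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  by_type <- setNames(integer(length(interaction_types())),
                      interaction_types())
  if (nrow(net$edges) > 0L) {
    tab <- table(net$edges$itype)
    by_type[names(tab)] <- as.integer(tab)
  }
  structure(list(
    label = net$label,
    n_nodes = nrow(net$nodes),
    n_genes = sum(net$nodes$kind == "gene"),
    n_proteins = sum(net$nodes$kind == "protein"),
    n_edges = nrow(net$edges),
    edges_by_type = by_type,
    n_self_loops = sum(net$edges$self_loop)
  ), class = "assoc_network_summary")
}

#' @export
print.assoc_network_summary <- function(x, ...) {
  cat("Network summary", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  nodes:", x$n_nodes, paste0("(", x$n_genes, " genes, ",
                                    x$n_proteins, " proteins)"), "\n")
  cat("  edges:", x$n_edges,
      if (x$n_self_loops > 0L) paste0("(", x$n_self_loops, " self-loops)"),
      "\n")
  tt <- x$edges_by_type[x$edges_by_type > 0L]
  for (nm in names(tt)) cat(sprintf("    %-26s %d\n", nm, tt[[nm]]))
  invisible(x)
}

#' @export
summary.assoc_network <- function(object, ...) network_summary(object)

#' Gene symbols present in a network
#'
#' @param net an [assoc_network()].
#' @param kind restrict to `"gene"` or `"protein"` vertices; `NULL` for both.
#' @return sorted character vector of unique symbols.
#' @export
network_symbols <- function(net, kind = NULL) {
  stopifnot(inherits(net, "assoc_network"))
  nodes <- net$nodes
  if (!is.null(kind)) nodes <- nodes[nodes$kind %in% kind, , drop = FALSE]
  sort(unique(nodes$symbol))
}
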