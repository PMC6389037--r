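# Independent brute-force oracles used to cross-check the package
# implementations on small instances.

# random simple undirected graph with named vertices; optionally resampled
# until connected
rnd_graph <- function(n, p, connected = FALSE, max_try = 200L) {
  for (i in seq_len(max_try)) {
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    if (!connected || igraph::is_connected(g)) return(g)
  }
  stop("could not generate a connected graph")
}

graph_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# all-pairs shortest distances by Floyd-Warshall on the adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dk <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], dk)
    }
  }
  d
}

oracle_degree_centrality <- function(g) {
  adj <- graph_adj(g)
  setNames(rowSums(adj) / (nrow(adj) - 1), igraph::V(g)$name)
}

oracle_closeness_centrality <- function(g) {
  adj <- graph_adj(g)
  d <- oracle_distances(adj)
  n <- nrow(adj)
  cc <- vapply(seq_len(n), function(i) {
    reach <- is.finite(d[i, ])
    r <- sum(reach)
    if (r <= 1L) return(0)
    ((r - 1) / sum(d[i, reach])) * ((r - 1) / (n - 1))
  }, numeric(1L))
  setNames(cc, igraph::V(g)$name)
}

# betweenness by exhaustive enumeration of all simple paths (n <= 8)
oracle_betweenness_centrality <- function(g) {
  adj <- graph_adj(g)
  n <- nrow(adj)
  d <- oracle_distances(adj)
  score <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible())
      }
      for (v in which(adj[u, ] > 0)) {
        if (!v %in% path) walk(c(path, v))
      }
    }
    walk(s)
    paths
  }
  for (s in seq_len(n - 1L)) {
    for (t in seq((s + 1L), n)) {
      if (!is.finite(d[s, t])) next
      sp <- Filter(function(p) length(p) - 1L == d[s, t], all_paths(s, t))
      sigma <- length(sp)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(sp, function(p) v %in% p, logical(1L)))
        score[v] <- score[v] + through / sigma
      }
    }
  }
  if (n >= 3L) score <- score * 2 / ((n - 1) * (n - 2))
  setNames(score, igraph::V(g)$name)
}

# edge set of a closed vertex sequence, as sorted "u|v" keys
cycle_edge_set <- function(cycle) {
  nxt <- c(cycle[-1L], cycle[1L])
  sort(paste(pmin(cycle, nxt), pmax(cycle, nxt), sep = "~"))
}

# exact GF(2) rank via elimination
gf2_rank <- function(m) {
  m <- m %% 2L
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(m))) {
    if (row > nrow(m)) break
    piv <- which(m[row:nrow(m), col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) m[c(piv, row), ] <- m[c(row, piv), ]
    hits <- which(m[, col] == 1L)
    for (r in setdiff(hits, row)) m[r, ] <- (m[r, ] + m[row, ]) %% 2L
    row <- row + 1L
    rank <- rank + 1L
  }
  rank
}

gf2_spans <- function(basis_sets, target_set) {
  universe <- sort(unique(c(unlist(basis_sets), target_set)))
  to_vec <- function(s) as.integer(universe %in% s)
  mat <- t(vapply(basis_sets, to_vec, integer(length(universe))))
  vec <- to_vec(target_set)
  gf2_rank(mat) == gf2_rank(rbind(mat, vec))
}

# exact two-sided Mann-Whitney p by enumeration over all group-1 position
# assignments (valid for untied pooled samples)
oracle_mwu <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Welch t-test from first principles
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

# hypergeometric upper tail by explicit summation of point masses
oracle_hyper_tail <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
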