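# Independent oracles and fixture helpers shared across test files.
# Oracles deliberately avoid the package's (and igraph's) algorithms:
# shortest paths by Floyd-Warshall on the adjacency matrix, modularity
# by a naive double loop.

# Dense adjacency matrix from an igraph, indexed by internal order.
adj_matrix_of <- function(g) {
  n <- igraph::vcount(g)
  A <- matrix(0L, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  A[el] <- 1L
  A[el[, c(2, 1), drop = FALSE]] <- 1L
  A
}

# All-pairs shortest path matrix by Floyd-Warshall.
oracle_distances <- function(g) {
  A <- adj_matrix_of(g)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Naive modularity: loop over all node pairs, Q = (1/2Ne) sum_ij
# (A_ij - k_i k_j / 2Ne) delta(c_i, c_j).
oracle_modularity <- function(g, mem) {
  A <- adj_matrix_of(g)
  deg <- rowSums(A)
  two_ne <- sum(deg)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mem[i] == mem[j]) q <- q + A[i, j] - deg[i] * deg[j] / two_ne
    }
  }
  q / two_ne
}

# Connected Erdos-Renyi-ish fixture with 0-based ids (LCC of a G(n, p)).
random_connected_graph <- function(n, p, seed) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
}

# Small pool of connected fixtures with <= 8 nodes for exhaustive checks.
small_fixture_pool <- function() {
  fx <- list(
    build_fixture("star", 5),
    build_fixture("path", 7),
    build_fixture("cycle", 8),
    build_fixture("two_cliques_bridge", 4),
    build_fixture("dyad"),
    build_fixture("grid", 2, 4))
  set.seed(424)
  for (s in 1:6) {
    g <- igraph::sample_gnp(8, 0.4)
    igraph::V(g)$name <- as.character(0:7)
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    if (igraph::vcount(g) >= 3) fx[[length(fx) + 1L]] <- g
  }
  fx
}

edge_set_of <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  u <- pmin(as.integer(el[, 1]), as.integer(el[, 2]))
  v <- pmax(as.integer(el[, 1]), as.integer(el[, 2]))
  sort(paste(u, v))
}
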