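# Small in-code fixtures shared across test files.

toy_table <- function(n = 10, p = 3, seed = 1, miss = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("g%02d", seq_len(n)),
                              sprintf("f%d", seq_len(p))))
  if (miss > 0) m[sample(length(m), miss)] <- NA
  feature_table(m)
}

# random simple undirected graph as an interaction_graph + adjacency matrix
random_graph_fixture <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  adj <- matrix(0L, n_nodes, n_nodes, dimnames = list(nodes, nodes))
  idx <- which(upper.tri(adj), arr.ind = TRUE)
  on <- runif(nrow(idx)) < p_edge
  from <- nodes[idx[on, 1]]
  to <- nodes[idx[on, 2]]
  adj[idx[on, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  g <- if (length(from)) interaction_graph(from, to) else
    interaction_graph(character(0), character(0))
  list(graph = g, adj = adj, nodes = nodes)
}

# independent shortest-path distances by BFS on the adjacency matrix
bfs_distances <- function(adj, start) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 &
                   is.infinite(dist))
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# two-sided Fisher p by exhaustive enumeration over the hypergeometric
# support (independent of the package's dhyper-based path)
enum_fisher_p <- function(a, b, c, d) {
  k <- a + b; m <- a + c; n <- b + d; N <- a + b + c + d
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x) {
    choose(m, x) * choose(n, k - x) / choose(N, k)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
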