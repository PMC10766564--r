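# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: power iteration instead of matrix inversion,
# explicit loops instead of vectorized cosine, and the textbook sum formula
# instead of stats::cor.

# RWR steady state by power iteration: p <- r e_i + (1 - r) W p
oracle_rwr <- function(network, restart_prob, tol = 1e-12) {
  a <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  w <- a / rep(colSums(a), each = nrow(a))
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- 1
    p <- e
    repeat {
      p_new <- restart_prob * e + (1 - restart_prob) * (w %*% p)
      if (max(abs(p_new - p)) < tol) break
      p <- p_new
    }
    out[i, ] <- p_new
  }
  dimnames(out) <- list(igraph::V(network)$name, igraph::V(network)$name)
  out
}

# cosine similarity by explicit double loop
oracle_cosine <- function(features) {
  n <- nrow(features)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(features[i, ]^2)); nj <- sqrt(sum(features[j, ]^2))
      s[i, j] <- if (ni == 0 || nj == 0) 0 else
        sum(features[i, ] * features[j, ]) / (ni * nj)
    }
  }
  s
}

# textbook Pearson correlation from the definition sums
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# shared-neighbour cosine by brute-force set intersection
oracle_local_similarity <- function(network) {
  nbrs <- lapply(igraph::V(network), function(v)
    sort(as.integer(igraph::neighbors(network, v))))
  n <- igraph::vcount(network)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      di <- length(nbrs[[i]]); dj <- length(nbrs[[j]])
      s[i, j] <- if (di == 0 || dj == 0) 0 else
        length(intersect(nbrs[[i]], nbrs[[j]])) / sqrt(di * dj)
    }
  }
  s
}

# small connected fixture graphs (all below 50 nodes) for property tests
fixture_graphs <- function() {
  random30 <- withr::with_seed(7L, {
    g <- igraph::sample_gnp(30, 0.15, directed = FALSE)
    while (!igraph::is_connected(g)) {
      g <- igraph::sample_gnp(30, 0.15, directed = FALSE)
    }
    igraph::V(g)$name <- sprintf("v%02d", 1:30)
    g
  })
  list(
    path2 = igraph::make_graph(~ a - b),
    path5 = igraph::make_ring(5, circular = FALSE),
    ring8 = igraph::make_ring(8),
    star7 = igraph::make_star(7, mode = "undirected"),
    tree_c3l2 = generate_cayley_tree(3, 2),
    grid3 = generate_cubic_grid(3),
    torus34 = generate_torus_lattice(3, 4),
    random30 = random30
  )
}
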