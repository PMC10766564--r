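test_that("cosine similarity matches hand-computed values and zero-row convention", {
  s <- cosine_similarity_matrix(rbind(a = c(1, 0), b = c(1, 1), c = c(0, 1),
                                      d = c(2, 0), e = c(0, 0)))
  expect_equal(s["a", "d"], 1)               # parallel rows
  expect_equal(s["a", "c"], 0)               # orthogonal rows
  expect_equal(s["a", "b"], 1 / sqrt(2))     # hand computation
  expect_equal(unname(diag(s)[1:4]), rep(1, 4))
  expect_equal(unname(s["e", ]), rep(0, 5))  # zero row: similarity 0, own diagonal too
  expect_equal(s["e", "e"], 0)
  expect_true(isSymmetric(unclass(s)))
  expect_error(cosine_similarity_matrix(matrix(nrow = 0, ncol = 2)), "non-empty")
})

test_that("cosine similarity agrees with a brute-force loop on random features", {
  for (seed in 1:3) {
    x <- withr::with_seed(seed, matrix(rnorm(15 * 4), 15, 4))
    x[seed, ] <- 0  # plant a zero row
    expect_equal(unclass(cosine_similarity_matrix(x)), oracle_cosine(x),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("RWR visiting frequencies solve the restart steady state", {
  p2 <- igraph::make_graph(~ a - b)
  p <- rwr_visiting_frequencies(p2, 0.5)
  # hand inversion of the 2x2 system: seed row (2/3, 1/3)
  expect_equal(unname(p["a", ]), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(unname(p["b", ]), c(1 / 3, 2 / 3), tolerance = 1e-12)

  # r = 1: the walker never leaves the seed
  expect_equal(rwr_visiting_frequencies(p2, 1), diag(2), ignore_attr = TRUE)

  expect_error(rwr_visiting_frequencies(p2, 0), "restart_prob")
  disconnected <- igraph::make_graph(~ a - b, c - d)
  expect_error(rwr_visiting_frequencies(disconnected, 0.5), "connected component")
})

test_that("RWR matrix inversion matches power iteration on all fixtures", {
  for (g in fixture_graphs()) {
    for (r in c(0.2, 0.5, 0.9)) {
      p <- rwr_visiting_frequencies(g, r)
      expect_true(all(p >= 0))
      expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
      expect_equal(unname(p), unname(oracle_rwr(g, r)), tolerance = 1e-8)
    }
  }
})

test_that("global similarity reflects graph symmetry and hand values", {
  p2 <- igraph::make_graph(~ a - b)
  s <- global_similarity(p2, restart_prob = 0.5)
  expect_equal(s["a", "b"], 0.8)  # cosine((2/3,1/3),(1/3,2/3)) = 4/5
  expect_equal(unname(diag(s)), c(1, 1))
  expect_identical(layout_kind(s), "global")

  # path of 3: the two endpoints are exchangeable by automorphism
  p3 <- igraph::make_graph(~ a - b - c)
  s3 <- global_similarity(p3, restart_prob = 0.4)
  expect_equal(s3["a", "b"], s3["c", "b"], tolerance = 1e-12)

  # torus: similarity depends only on the toroidal displacement
  tor <- generate_torus_lattice(4, 4)
  st <- global_similarity(tor, restart_prob = 0.3)
  ids <- igraph::V(tor)$name
  at <- function(r, c) st["0_0", sprintf("%d_%d", r %% 4, c %% 4)]
  shifted <- st["1_2", sprintf("%d_%d", (1 + 1) %% 4, (2 + 0) %% 4)]
  expect_equal(at(1, 0), shifted, tolerance = 1e-10)
  expect_equal(at(0, 1), at(0, 3), tolerance = 1e-10)
})

test_that("local similarity equals the shared-neighbour cosine oracle", {
  p2 <- igraph::make_graph(~ a - b)
  expect_equal(local_similarity(p2)["a", "b"], 0)  # no shared neighbours

  cyc4 <- igraph::make_ring(4)
  expect_equal(local_similarity(cyc4)[1, 3], 1)    # identical neighbourhoods

  # bipartite parity: opposite-parity nodes in the cubic grid share no neighbours
  g <- generate_cubic_grid(3)
  s <- local_similarity(g)
  parity <- sapply(strsplit(igraph::V(g)$name, "_"),
                   function(v) sum(as.integer(v)) %% 2)
  opposite <- outer(parity, parity, "!=")
  expect_true(all(s[opposite] == 0))

  for (g in fixture_graphs()[c("path5", "star7", "torus34", "random30")]) {
    expect_equal(unname(unclass(local_similarity(g))),
                 oracle_local_similarity(g), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("importance features capture centrality structure", {
  # torus: every node equivalent, raw centralities constant
  feats <- importance_features(generate_torus_lattice(4, 5), rescale = FALSE)
  expect_lt(max(apply(feats, 2, function(col) diff(range(col)))), 1e-9)

  # after unit-max rescaling, constant columns map to 1 and rows stay identical
  scaled <- importance_features(generate_torus_lattice(4, 5))
  expect_equal(unname(scaled), matrix(1, 20, 4), tolerance = 1e-9)

  # star centre dominates every raw centrality
  star <- igraph::make_star(7, mode = "undirected")
  raw <- importance_features(star, rescale = FALSE)
  expect_true(all(raw[1, ] > apply(raw[-1, ], 2, max)))

  # path of 3: normalized betweenness is 1 at the centre, 0 at the endpoints
  p3 <- igraph::make_graph(~ a - b - c)
  expect_equal(unname(importance_features(p3, rescale = FALSE)[, "betweenness"]),
               c(0, 1, 0))
})

test_that("importance similarity is exactly 1 within equivalent node classes", {
  tor <- generate_torus_lattice(4, 5)
  st <- importance_similarity(tor)
  expect_equal(unname(st), matrix(1, 20, 20), tolerance = 1e-9,
               ignore_attr = TRUE)

  tree <- generate_cayley_tree(3, 3)
  s <- importance_similarity(tree)
  shell <- as.integer(sub("_.*", "", igraph::V(tree)$name))
  for (l in unique(shell)) {
    members <- which(shell == l)
    expect_equal(unname(s[members, members, drop = FALSE]),
                 matrix(1, length(members), length(members)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("functional similarity validates binarity and matches hand values", {
  ann <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0),
               d = c(0, 0, 0))
  s <- functional_similarity(ann)
  expect_equal(s["a", "b"], 0.5)       # 1 / (sqrt(2) sqrt(2))
  expect_equal(s["a", "c"], 1)         # identical annotations
  expect_equal(unname(s["d", ]), rep(0, 4))  # empty annotation set
  expect_error(functional_similarity(rbind(c(1, 2))), "binary")
})

test_that("combined layout interpolates between global and functional", {
  g <- generate_cubic_grid(3)
  ann <- generate_block_annotations(n_groups = 3, nodes_per_group = 9,
                                    n_features = 9, seed = 11,
                                    node_ids = igraph::V(g)$name)
  s_glob <- global_similarity(g)
  s_func <- functional_similarity(ann)

  # m = 0: annotation columns vanish, S_comb == S_glob entrywise
  s0 <- combined_similarity(g, ann, m = 0)
  expect_equal(unclass(s0), unclass(s_glob), tolerance = 1e-12,
               ignore_attr = TRUE)

  # huge m: annotation columns dominate the inner products
  s_inf <- combined_similarity(g, ann, m = 1e6)
  expect_lt(max(abs(s_inf - s_func)), 1e-3)

  # all-zero annotations contribute nothing at any m
  zeros <- matrix(0L, igraph::vcount(g), 4,
                  dimnames = list(igraph::V(g)$name, NULL))
  expect_equal(unclass(combined_similarity(g, zeros, m = 1)),
               unclass(s_glob), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(combined_features(g, ann, m = -1), "non-negative")
})

test_that("all layout similarity matrices share the contract invariants", {
  g <- fixture_graphs()$random30
  ann <- generate_block_annotations(n_groups = 3, nodes_per_group = 10,
                                    n_features = 6, seed = 2,
                                    node_ids = igraph::V(g)$name)
  mats <- list(global_similarity(g), local_similarity(g),
               importance_similarity(g), functional_similarity(ann),
               combined_similarity(g, ann, m = 2))
  for (s in mats) {
    expect_true(isSymmetric(unclass(s), tol = 1e-12))
    expect_true(all(s >= 0 - 1e-12 & s <= 1 + 1e-12))
    nz <- rowSums(s != 0) > 0
    expect_true(all(abs(diag(unclass(s))[nz] - 1) < 1e-12))
  }
})
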