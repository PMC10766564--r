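test_that("all-pairs shortest paths count every unordered pair once", {
  p2 <- igraph::make_graph(~ a - b)
  pairs <- all_pairs_shortest_paths(p2)
  expect_equal(pairs$n_pairs, 1)
  expect_equal(pairs$d_sp, 1L)

  g <- generate_cubic_grid(4)
  pairs <- all_pairs_shortest_paths(g)
  expect_equal(length(pairs$d_sp), 64 * 63 / 2)
  # pair-count conservation across distances
  expect_equal(sum(table(pairs$d_sp)), 64 * 63 / 2)
  expect_equal(max(pairs$d_sp), 9)  # opposite corners of the 4-grid

  expect_error(all_pairs_shortest_paths(igraph::make_graph(~ a - b, c - d)),
               "disconnected")
})

test_that("layout distances are exact and isometry-invariant", {
  sq <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), d = c(1, 1))
  d <- layout_distances(sq)
  expect_equal(sort(d), c(1, 1, 1, 1, sqrt(2), sqrt(2)))

  expect_equal(layout_distances(matrix(0, 5, 2,
                                       dimnames = list(letters[1:5], NULL))),
               rep(0, 10))

  # translation + rotation leave distances unchanged
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- sweep(sq %*% rot, 2, c(3, -5), "+")
  expect_equal(layout_distances(moved), d, tolerance = 1e-9)
})

test_that("pearson correlation implements the pair-sum formula", {
  expect_equal(pearson_correlation(list(d_sp = c(1, 2, 5),
                                        d_euc = 2 * c(1, 2, 5))), 1)
  expect_equal(pearson_correlation(list(d_sp = c(1, 2, 3),
                                        d_euc = c(3, 2, 1))), -1)
  # frozen value from the textbook-formula oracle
  expect_equal(pearson_correlation(list(d_sp = c(1, 1, 2, 3),
                                        d_euc = c(1.0, 1.2, 2.1, 2.9))),
               0.9940534656, tolerance = 1e-9)
  expect_error(pearson_correlation(list(d_sp = c(1, 1), d_euc = c(1, 2))),
               "zero variance")
})

test_that("pearson correlation equals the independent oracle on random input", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, list(a = rnorm(200), b = rnorm(200)))
    expect_equal(pearson_correlation(list(d_sp = x$a, d_euc = x$b)),
                 oracle_pearson(x$a, x$b), tolerance = 1e-12)
  }
})

test_that("benchmark_layout combines distances, quartiles and provenance", {
  # path at canonical integer positions: d_euc == d_sp, r = 1
  path <- igraph::make_graph(~ a - b - c - d - e)
  coords <- cbind(x = 0:4, y = 0)
  rownames(coords) <- igraph::V(path)$name
  bench <- benchmark_layout(path, coords)
  expect_equal(bench$pearson_r, 1)
  expect_equal(bench$by_distance$n, c(4, 3, 2, 1))
  expect_equal(bench$by_distance$median, 1:4)
  expect_equal(sum(bench$by_distance$n), bench$n_pairs)

  # canonical lattice coordinates of a grid against the brute-force oracle
  g <- generate_cubic_grid(4)
  xyz <- do.call(rbind, lapply(strsplit(igraph::V(g)$name, "_"), as.integer))
  rownames(xyz) <- igraph::V(g)$name
  bench <- benchmark_layout(g, xyz)
  pairs <- bench$pairs
  expect_equal(bench$pearson_r, oracle_pearson(pairs$d_sp, pairs$d_euc),
               tolerance = 1e-12)

  # scale invariance of the correlation
  bench10 <- benchmark_layout(g, xyz * 10)
  expect_equal(bench10$pearson_r, bench$pearson_r, tolerance = 1e-12)

  # shuffled coordinate rows are realigned by node identifier
  perm <- withr::with_seed(1, sample(nrow(xyz)))
  expect_equal(benchmark_layout(g, xyz[perm, ])$pearson_r, bench$pearson_r)
})

test_that("xy distance mode benchmarks a topographic map by its base plane", {
  g <- generate_torus_lattice(4, 5)
  e2 <- embed_similarity(global_similarity(g, 0.3),
                         embedding_config(geometry = "plane2d", seed = 1))
  topo <- make_topographic(e2, generate_node_scalar(g, "uniform-random", seed = 2))
  base <- benchmark_layout(g, make_portrait(e2))
  expect_equal(benchmark_layout(g, topo, dims = "xy")$pearson_r,
               base$pearson_r, tolerance = 1e-12)
})

test_that("force-directed baseline is deterministic given a seed", {
  g <- generate_cubic_grid(3)
  f1 <- layout_force_directed(g, dim = 2, niter = 200, seed = 5)
  f2 <- layout_force_directed(g, dim = 2, niter = 200, seed = 5)
  expect_identical(f1$coordinates, f2$coordinates)
  expect_equal(f1$provenance$layout_kind, "force_directed")
  expect_equal(f1$map_type, "portrait2d")
})
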