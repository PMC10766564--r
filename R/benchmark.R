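#' Layout-quality benchmark
#'
#' How faithfully does a layout reproduce network distances? For every
#' unordered node pair the benchmark compares the shortest-path length
#' `d_sp` in the network with the Euclidean distance `d_euc` between the
#' nodes' layout positions, and quantifies the agreement by their Pearson
#' correlation over all `N (N - 1) / 2` pairs. A per-distance summary
#' (count and minimum / quartiles / maximum of `d_euc` at each `d_sp`)
#' shows where a layout distorts.
#'
#' @param network connected, simple, undirected [igraph::igraph] object.
#' @return `all_pairs_shortest_paths()` returns a list of class
#'   `cartonet_distance_pairs` with integer pair indices `i`, `j`
#'   (`i > j`, column-major lower triangle order), the distances and the
#'   node identifiers.
#' @examples
#' g <- generate_torus_lattice(3, 3)
#' pairs <- all_pairs_shortest_paths(g)
#' pairs$n_pairs  # 9 * 8 / 2
#' @export
all_pairs_shortest_paths <- function(network) {
  network <- assert_network(network)
  if (!igraph::is_connected(network)) {
    comps <- igraph::components(network)
    abort_input(paste(
      "network is disconnected (%d components; e.g. nodes '%s' and '%s' have",
      "no connecting path); benchmark each component separately"),
      comps$no,
      node_ids(network)[match(1, comps$membership)],
      node_ids(network)[match(2, comps$membership)])
  }
  d <- igraph::distances(network)
  lower <- lower.tri(d)
  n <- nrow(d)
  structure(
    list(i = row(d)[lower], j = col(d)[lower],
         d_sp = as.integer(d[lower]), d_euc = NULL,
         node_ids = node_ids(network), n_pairs = n * (n - 1) / 2),
    class = "cartonet_distance_pairs")
}

#' @rdname all_pairs_shortest_paths
#' @param cartograph a `cartonet_map`, a `cartonet_embedding`, or a bare
#'   coordinate matrix with node identifiers as row names.
#' @param dims `"native"` (default) computes distances in the map's full
#'   geometry; `"xy"` restricts to the first two coordinates, e.g. to judge
#'   a topographic map by its base plane.
#' @return `layout_distances()` returns the pairwise Euclidean distances in
#'   the same column-major lower-triangle pair order used by
#'   `all_pairs_shortest_paths()`.
#' @export
layout_distances <- function(cartograph, dims = c("native", "xy")) {
  dims <- match.arg(dims)
  coords <- map_coordinates(cartograph)
  if (!all(is.finite(coords))) abort_input("layout coordinates must be finite")
  if (dims == "xy") coords <- coords[, 1:2, drop = FALSE]
  as.vector(stats::dist(coords))
}

map_coordinates <- function(x) {
  if (inherits(x, "cartonet_map")) x$coordinates
  else if (inherits(x, "cartonet_embedding")) x$coordinates
  else if (is.matrix(x)) x
  else abort_input("expected a cartonet_map, cartonet_embedding or coordinate matrix")
}

#' @rdname all_pairs_shortest_paths
#' @param pairs a `cartonet_distance_pairs` object whose `d_sp` and `d_euc`
#'   are both filled in (as produced by [benchmark_layout()]), or any list
#'   with numeric `d_sp` and `d_euc` of equal length.
#' @return `pearson_correlation()` returns the Pearson correlation
#'   coefficient between the two distance series.
#' @export
pearson_correlation <- function(pairs) {
  d_sp <- pairs$d_sp; d_euc <- pairs$d_euc
  if (is.null(d_sp) || is.null(d_euc) || length(d_sp) != length(d_euc)) {
    abort_input("`pairs` must carry d_sp and d_euc of equal length")
  }
  if (length(d_sp) < 2) abort_input("at least two pairs are required")
  if (stats::var(d_sp) == 0 || stats::var(d_euc) == 0) {
    abort_input("correlation is undefined: one of the distance series has zero variance")
  }
  stats::cor(d_sp, d_euc)
}

#' @rdname all_pairs_shortest_paths
#' @return `benchmark_layout()` returns a list of class
#'   `cartonet_benchmark`: `pearson_r`, `n_pairs`, the filled-in `pairs`,
#'   a `by_distance` data frame (`d_sp`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max` of `d_euc`), and the map's provenance.
#' @examples
#' # a path laid out at its canonical integer positions is reproduced exactly
#' path <- igraph::make_graph(~ a - b - c - d)
#' coords <- cbind(x = 0:3, y = 0)
#' rownames(coords) <- igraph::V(path)$name
#' benchmark_layout(path, coords)$pearson_r  # 1
#' @export
benchmark_layout <- function(network, cartograph, dims = c("native", "xy")) {
  pairs <- all_pairs_shortest_paths(network)
  coords <- map_coordinates(cartograph)
  ids <- node_ids(assert_network(network))
  if (!is.null(rownames(coords))) {
    absent <- setdiff(ids, rownames(coords))
    if (length(absent) > 0) {
      abort_input("cartograph lacks coordinates for %d network node(s), e.g. '%s'",
                  length(absent), absent[1])
    }
    coords <- coords[ids, , drop = FALSE]
  } else if (nrow(coords) != length(ids)) {
    abort_input("cartograph has %d rows but the network has %d nodes",
                nrow(coords), length(ids))
  }
  pairs$d_euc <- layout_distances(coords, dims = dims)
  by_dist <- tapply(pairs$d_euc, pairs$d_sp, function(v) {
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    c(n = length(v), min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  })
  by_dist <- data.frame(d_sp = as.integer(names(by_dist)),
                        do.call(rbind, by_dist), row.names = NULL)
  structure(
    list(pearson_r = pearson_correlation(pairs),
         n_pairs = pairs$n_pairs,
         pairs = pairs,
         by_distance = by_dist,
         provenance = if (inherits(cartograph, "cartonet_map"))
           cartograph$provenance else NULL),
    class = "cartonet_benchmark")
}

#' @export
print.cartonet_benchmark <- function(x, ...) {
  cat(sprintf("<cartonet_benchmark> %d node pairs, Pearson r = %.4f\n",
              x$n_pairs, x$pearson_r))
  cat(sprintf("  shortest-path distances %d..%d\n",
              min(x$by_distance$d_sp), max(x$by_distance$d_sp)))
  invisible(x)
}

#' Force-directed baseline layout
#'
#' Thin adapter around the Fruchterman-Reingold spring layout in
#' \pkg{igraph}, provided as an external baseline for [benchmark_layout()]
#' comparisons — not a similarity-driven cartograph. Run with enough
#' iterations to converge (the default 2000 is converged for lattices of a
#' thousand nodes); the iteration count is recorded in the provenance.
#'
#' @inheritParams all_pairs_shortest_paths
#' @param dim 2 or 3 layout dimensions (default 3).
#' @param niter iterations of the spring optimizer (default 2000).
#' @param seed random seed (default 42).
#' @return A `cartonet_map` portrait whose provenance records
#'   `layout_kind = "force_directed"`.
#' @export
layout_force_directed <- function(network, dim = 3, niter = 2000, seed = 42) {
  network <- assert_network(network)
  if (!dim %in% c(2, 3)) abort_input("`dim` must be 2 or 3")
  coords <- withr::with_seed(as.integer(seed),
    igraph::layout_with_fr(network, dim = dim, niter = niter))
  rownames(coords) <- node_ids(network)
  m <- new_map(coords, if (dim == 2) "portrait2d" else "portrait3d",
               layout_kind = "force_directed")
  m$provenance$method <- "fruchterman_reingold"
  m$provenance$seed <- as.integer(seed)
  m$provenance$niter <- niter
  m
}
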