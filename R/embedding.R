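#' Embedding configuration
#'
#' Collects the dimensionality-reduction settings used by
#' [embed_similarity()] and [embed_sphere()]. Two reducer families are
#' supported, `"tsne"` (Barnes-Hut t-SNE via \pkg{Rtsne}) and `"umap"`
#' (via \pkg{uwot}); both read each node's row of the similarity matrix as
#' its feature vector by default (`input = "similarity"`), or the
#' dissimilarity `1 - S` as a precomputed distance (`input = "distance"`).
#'
#' Defaults favour global-structure preservation, which is what the layouts
#' encode: the embedding is initialized from the leading principal
#' components of the input (`init = "pca"`) and t-SNE uses a generous
#' perplexity of `min(100, floor((N - 1) / 3))`. All stochastic steps are
#' governed by `seed`, so a configuration fully determines the output.
#'
#' @param method `"tsne"` or `"umap"`.
#' @param geometry `"plane2d"`, `"space3d"`, or `"sphere"` (3D coordinates
#'   radially projected to the unit sphere).
#' @param seed integer random seed (default 42).
#' @param perplexity t-SNE perplexity; default `min(100, floor((N - 1) / 3))`.
#' @param n_neighbors UMAP neighbourhood size; default
#'   `min(100, max(2, floor((N - 1) / 3)))`.
#' @param n_iter optimization iterations: t-SNE gradient-descent iterations
#'   (default 1000) or UMAP epochs (default 500 when `NULL`).
#' @param input `"similarity"` (rows as feature vectors, default) or
#'   `"distance"` (feed `1 - S` as a precomputed distance matrix).
#' @param init `"pca"` (default) or `"random"` embedding initialization.
#' @return A list of class `cartonet_embedding_config`.
#' @export
embedding_config <- function(method = c("tsne", "umap"),
                             geometry = c("plane2d", "space3d", "sphere"),
                             seed = 42L,
                             perplexity = NULL,
                             n_neighbors = NULL,
                             n_iter = NULL,
                             input = c("similarity", "distance"),
                             init = c("pca", "random")) {
  method <- match.arg(method)
  geometry <- match.arg(geometry)
  input <- match.arg(input)
  init <- match.arg(init)
  for (nm in c("perplexity", "n_neighbors", "n_iter")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1 || v <= 0)) {
      abort_input("`%s` must be a positive number", nm)
    }
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    abort_input("`seed` must be a single integer")
  }
  structure(
    list(method = method, geometry = geometry, seed = as.integer(seed),
         perplexity = perplexity, n_neighbors = n_neighbors,
         n_iter = n_iter, input = input, init = init),
    class = "cartonet_embedding_config")
}

#' @export
print.cartonet_embedding_config <- function(x, ...) {
  cat(sprintf("<cartonet_embedding_config> %s -> %s (seed %d, init %s, input %s)\n",
              x$method, x$geometry, x$seed, x$init, x$input))
  invisible(x)
}

resolved_config <- function(config, n) {
  config$dims <- if (config$geometry == "plane2d") 2L else 3L
  config$perplexity <- config$perplexity %||%
    min(100, max(1, floor((n - 1) / 3)))
  config$n_neighbors <- config$n_neighbors %||%
    min(100, max(2, floor((n - 1) / 3)))
  config$n_iter <- config$n_iter %||%
    (if (config$method == "tsne") 1000L else 500L)
  config
}

#' Embed a similarity matrix into 2D/3D coordinates
#'
#' The dimensionality-reduction step of the pipeline: nodes with similar
#' feature vectors — hence similar rows of the similarity matrix — are
#' placed close together in 2D or 3D Euclidean space, or on the unit sphere.
#' Euclidean coordinates are post-normalized to zero centroid and unit
#' root-mean-square radius so downstream map scaling is well defined.
#'
#' Given the same similarity matrix and configuration (including the seed)
#' the result is identical between calls. A fully degenerate input (all
#' feature rows identical, e.g. an all-ones similarity matrix) carries no
#' information to lay out; the embedding then collapses to the origin with
#' a warning rather than failing.
#'
#' @param similarity symmetric similarity matrix, typically from one of the
#'   layout constructors ([global_similarity()] and friends).
#' @param config an [embedding_config()].
#' @return A list of class `cartonet_embedding` with elements `coordinates`
#'   (`N x d`, node identifiers as row names), `geometry`, `method`,
#'   `layout_kind`, `config`; sphere embeddings additionally carry
#'   `latitude` and `longitude` (radians).
#' @examples
#' s <- global_similarity(generate_torus_lattice(4, 4), 0.3)
#' emb <- embed_similarity(s, embedding_config(geometry = "plane2d", seed = 1))
#' dim(emb$coordinates)
#' @export
embed_similarity <- function(similarity, config = embedding_config()) {
  if (!inherits(config, "cartonet_embedding_config")) {
    abort_input("`config` must come from embedding_config()")
  }
  x <- unclass(as.matrix(similarity))
  n <- nrow(x)
  if (n < 4) abort_input("at least 4 nodes are required for an embedding")
  if (!all(is.finite(x))) abort_input("`similarity` contains non-finite entries")
  config <- resolved_config(config, n)

  ids <- rownames(x)
  degenerate <- all(abs(sweep(x, 2, x[1, ])) < 1e-12)
  if (degenerate) {
    warning("all similarity rows are identical; embedding collapses to the origin",
            call. = FALSE)
    coords <- matrix(0, n, config$dims)
  } else {
    coords <- withr::with_seed(config$seed, run_reducer(x, config))
  }
  if (config$geometry != "sphere") {
    coords <- normalize_coords(coords)
  }
  rownames(coords) <- ids
  emb <- structure(
    list(coordinates = coords, geometry = config$geometry,
         method = config$method,
         layout_kind = attr(similarity, "layout_kind"),
         config = config),
    class = "cartonet_embedding")
  if (config$geometry == "sphere") emb <- project_to_sphere(emb)
  emb
}

run_reducer <- function(x, config) {
  n <- nrow(x)
  as_distance <- config$input == "distance"
  feed <- if (as_distance) stats::as.dist(1 - x) else x
  init_coords <- NULL
  if (config$init == "pca" && config$method == "tsne") {
    # t-SNE convention: PCA directions shrunk to sd 1e-4 as the starting map
    pcs <- stats::prcomp(x, rank. = config$dims)$x
    spread <- stats::sd(pcs[, 1])
    init_coords <- if (spread > 0) pcs / spread * 1e-4 else NULL
  }
  if (config$method == "tsne") {
    perp <- min(config$perplexity, floor((n - 1) / 3))
    if (perp < 1) abort_input("too few nodes for the configured perplexity")
    args <- list(X = feed, dims = config$dims, perplexity = perp,
                 max_iter = config$n_iter, theta = 0.5,
                 check_duplicates = FALSE, pca = !as_distance,
                 is_distance = as_distance, num_threads = 1L)
    if (!is.null(init_coords)) args$Y_init <- init_coords
    do.call(Rtsne::Rtsne, args)$Y
  } else {
    uwot::umap(feed, n_components = config$dims,
               n_neighbors = min(config$n_neighbors, n - 1),
               n_epochs = config$n_iter,
               init = if (config$init == "pca") "pca" else "random",
               n_threads = 1L, n_sgd_threads = 0L, verbose = FALSE)
  }
}

normalize_coords <- function(coords) {
  coords <- sweep(coords, 2, colMeans(coords))
  rms <- sqrt(mean(rowSums(coords^2)))
  if (rms > 0) coords <- coords / rms
  coords
}

#' @rdname embed_similarity
#' @details `embed_sphere()` runs the 3D reduction, centres the coordinates
#'   at their centroid and projects them radially onto the unit sphere — a
#'   backend-independent construction. Latitude is `asin(z)` in
#'   `[-pi/2, pi/2]`, longitude `atan2(y, x)` in `(-pi, pi]`.
#' @export
embed_sphere <- function(similarity, config = embedding_config(geometry = "sphere")) {
  config$geometry <- "sphere"
  embed_similarity(similarity, config)
}

project_to_sphere <- function(emb) {
  coords <- sweep(emb$coordinates, 2, colMeans(emb$coordinates))
  norms <- sqrt(rowSums(coords^2))
  zero <- norms < 1e-12
  coords[zero, ] <- matrix(rep(c(0, 0, 1), sum(zero)), ncol = 3, byrow = TRUE)
  norms[zero] <- 1
  coords <- coords / norms
  emb$coordinates <- coords
  emb$latitude <- asin(pmin(1, pmax(-1, coords[, 3])))
  emb$longitude <- atan2(coords[, 2], coords[, 1])
  emb
}

#' @export
print.cartonet_embedding <- function(x, ...) {
  cat(sprintf("<cartonet_embedding> %d nodes, %s via %s (layout kind: %s, seed %d)\n",
              nrow(x$coordinates), x$geometry, x$method,
              x$layout_kind %||% "unspecified", x$config$seed))
  invisible(x)
}
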