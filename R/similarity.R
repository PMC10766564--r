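#' Cosine similarity matrix of node feature vectors
#'
#' Every layout in the framework shares one conversion: an `N x F` node
#' feature matrix (visiting frequencies, adjacency columns, centrality
#' profiles or annotations) is turned into an `N x N` matrix of pairwise
#' cosine similarities, `S[n, m] = <v_n, v_m> / (||v_n|| ||v_m||)`.
#'
#' A node whose feature vector is all zero carries no information; by
#' convention its similarity to every node — including itself — is 0, which
#' keeps the matrix finite. The result is exactly symmetric, clipped to
#' `[-1, 1]`, with diagonal 1 for every nonzero row.
#'
#' @param features numeric matrix, one row per node (row names are node
#'   identifiers).
#' @param layout_kind optional label (`"global"`, `"local"`, `"importance"`,
#'   `"functional"`, `"combined"`) recorded on the result and propagated
#'   into map provenance.
#' @return A numeric `N x N` matrix of class `cartonet_similarity` with a
#'   `layout_kind` attribute.
#' @examples
#' cosine_similarity_matrix(rbind(a = c(1, 0), b = c(1, 1)))[1, 2]  # 1/sqrt(2)
#' @export
cosine_similarity_matrix <- function(features, layout_kind = NULL) {
  features <- as.matrix(features)
  if (length(features) == 0 || ncol(features) < 1 || nrow(features) < 1) {
    abort_input("`features` must be a non-empty numeric matrix")
  }
  if (!is.numeric(features) || !all(is.finite(features))) {
    abort_input("`features` must be finite and numeric")
  }
  norms <- sqrt(rowSums(features^2))
  nz <- norms > 0
  scaled <- features
  scaled[nz, ] <- features[nz, , drop = FALSE] / norms[nz]
  scaled[!nz, ] <- 0
  s <- tcrossprod(scaled)
  s <- (s + t(s)) / 2
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s)[nz] <- 1
  diag(s)[!nz] <- 0
  dimnames(s) <- list(rownames(features), rownames(features))
  new_similarity(s, layout_kind)
}

new_similarity <- function(values, layout_kind = NULL) {
  structure(values, layout_kind = layout_kind,
            class = c("cartonet_similarity", class(matrix())))
}

#' @export
print.cartonet_similarity <- function(x, ...) {
  cat(sprintf("<cartonet_similarity> %d x %d, layout kind: %s\n",
              nrow(x), ncol(x), layout_kind(x) %||% "unspecified"))
  invisible(x)
}

#' @rdname cosine_similarity_matrix
#' @param similarity a `cartonet_similarity` matrix.
#' @export
layout_kind <- function(similarity) attr(similarity, "layout_kind")

#' Random walk with restart visiting frequencies
#'
#' Seeds a random walk with restart (RWR) at each node in turn and computes
#' the steady-state probability of finding the walker at every other node.
#' At each step the walker either restarts at its seed (probability
#' `restart_prob`) or moves to a uniformly chosen neighbour. With `W` the
#' column-normalized adjacency matrix, the visiting-frequency vector of seed
#' `i` has the closed form
#' `p_i = r (I - (1 - r) W)^{-1} e_i`,
#' obtained here by a single dense solve shared by all seeds. Each `p_i` is
#' a probability distribution (non-negative, sums to 1) whose decay with
#' network distance makes it a high-resolution descriptor of the seed's
#' global position — the feature vector of the global layout.
#'
#' @param network connected, simple, undirected [igraph::igraph] object.
#' @param restart_prob restart probability `r` in `(0, 1]`; smaller values
#'   diffuse further. Default 0.2.
#' @return `N x N` matrix whose row `i` is the visiting-frequency vector of
#'   seed node `i` (rows and columns in network node order).
#' @examples
#' p <- rwr_visiting_frequencies(generate_torus_lattice(3, 3), 0.5)
#' rowSums(p)  # all 1
#' @export
rwr_visiting_frequencies <- function(network, restart_prob = 0.2) {
  network <- assert_network(network, connected = TRUE)
  if (!is.numeric(restart_prob) || length(restart_prob) != 1 ||
      restart_prob <= 0 || restart_prob > 1) {
    abort_input("`restart_prob` must lie in (0, 1]")
  }
  n <- igraph::vcount(network)
  a <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  w <- a / rep(colSums(a), each = n)  # column-stochastic transition matrix
  # p_i = r (I - (1-r) W)^{-1} e_i: seed i's frequencies are column i,
  # so the per-seed feature matrix (rows = seeds) is the transpose
  p <- restart_prob * solve(diag(n) - (1 - restart_prob) * w)
  p <- t(p)
  dimnames(p) <- list(node_ids(network), node_ids(network))
  p
}

#' Layout similarity matrices
#'
#' Each layout family encodes a different node characteristic into the
#' feature matrix before the common cosine step:
#'
#' * `global_similarity()` — rows are RWR visiting-frequency vectors
#'   ([rwr_visiting_frequencies()]); similar vectors mean similar global
#'   network position, so the embedding reproduces pairwise network
#'   distances.
#' * `local_similarity()` — rows are adjacency-matrix columns; two nodes are
#'   similar when they share neighbours, which exposes bi- and multipartite
#'   structure (nodes of opposite parity in a bipartite lattice share no
#'   neighbours and get similarity exactly 0).
#' * `importance_similarity()` — rows are 4-component centrality profiles
#'   ([importance_features()]); nodes of equal structural importance
#'   coincide.
#' * `functional_similarity()` — rows are binary annotation vectors, e.g.
#'   gene-disease associations; the layout is driven purely by external
#'   features.
#' * `combined_similarity()` — visiting frequencies concatenated with
#'   annotation columns scaled by `m >= 0`, interpolating from purely
#'   structural (`m = 0`) to annotation-dominated layouts.
#'
#' @inheritParams rwr_visiting_frequencies
#' @return A `cartonet_similarity` matrix (see [cosine_similarity_matrix()]).
#' @examples
#' g <- generate_cubic_grid(3)
#' s <- global_similarity(g, restart_prob = 0.5)
#' s[1, 1]
#' @export
global_similarity <- function(network, restart_prob = 0.2) {
  p <- rwr_visiting_frequencies(network, restart_prob)
  cosine_similarity_matrix(p, layout_kind = "global")
}

#' @rdname global_similarity
#' @export
local_similarity <- function(network) {
  network <- assert_network(network)
  if (igraph::vcount(network) < 2) {
    abort_input("`network` must have at least 2 nodes")
  }
  a <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  cross <- as.matrix(Matrix::crossprod(a))  # shared-neighbour counts
  deg <- Matrix::diag(cross)
  norms <- sqrt(deg)
  nz <- norms > 0
  s <- cross
  s[nz, ] <- s[nz, , drop = FALSE] / norms[nz]
  s[, nz] <- sweep(s[, nz, drop = FALSE], 2, norms[nz], "/")
  s[!nz, ] <- 0
  s[, !nz] <- 0
  s[s > 1] <- 1
  diag(s)[nz] <- 1
  dimnames(s) <- list(node_ids(network), node_ids(network))
  new_similarity(s, "local")
}

#' Centrality profile features for the importance layout
#'
#' Computes for every node the four classical centralities — degree,
#' closeness (inverse average shortest-path distance), betweenness
#' (normalized fraction of shortest paths passing through the node) and
#' eigenvector centrality — as an `N x 4` feature matrix.
#'
#' Raw centralities live on wildly different scales (betweenness dwarfs a
#' degree of a few), so by default each column is rescaled to `[0, 1]` by
#' dividing by its maximum before the cosine step. Unit-max scaling (rather
#' than min-max) keeps equal centrality profiles equal: min-max would map
#' every node class sitting at the minimum of all four columns — the leaves
#' of a Cayley tree — to the zero vector, whose cosine similarity is 0 by
#' convention even within the class. An all-zero column (betweenness on a
#' complete graph) is left at zero. Set `rescale = FALSE` for the raw
#' centrality vectors.
#'
#' @inheritParams rwr_visiting_frequencies
#' @param rescale divide each centrality column by its maximum
#'   (default `TRUE`).
#' @return `N x 4` matrix with columns `degree`, `closeness`, `betweenness`,
#'   `eigenvector` and node identifiers as row names.
#' @export
importance_features <- function(network, rescale = TRUE) {
  network <- assert_network(network, connected = TRUE)
  eig <- igraph::eigen_centrality(
    network, options = list(maxiter = 10000L, tol = 1e-10))
  feats <- cbind(
    degree = igraph::degree(network),
    closeness = igraph::closeness(network, normalized = TRUE),
    betweenness = igraph::betweenness(network, normalized = TRUE),
    eigenvector = eig$vector
  )
  if (rescale) {
    feats <- apply(feats, 2, function(col) {
      m <- max(col)
      if (m > 0) col / m else col
    })
  }
  rownames(feats) <- node_ids(network)
  feats
}

#' @rdname global_similarity
#' @inheritParams importance_features
#' @export
importance_similarity <- function(network, rescale = TRUE) {
  cosine_similarity_matrix(importance_features(network, rescale = rescale),
                           layout_kind = "importance")
}

#' @rdname global_similarity
#' @param annotations binary node-by-feature matrix with node identifiers as
#'   row names in network node order (see [read_annotations()] and
#'   [generate_block_annotations()]). A node with no annotations gets
#'   similarity 0 to every node.
#' @export
functional_similarity <- function(annotations) {
  annotations <- as.matrix(annotations)
  if (!all(annotations %in% c(0, 1))) {
    bad <- which(!(annotations %in% c(0, 1)))[1]
    abort_input("`annotations` must be binary; offending entry at row %d, column %d",
                (bad - 1) %% nrow(annotations) + 1,
                (bad - 1) %/% nrow(annotations) + 1)
  }
  cosine_similarity_matrix(annotations, layout_kind = "functional")
}

#' @rdname global_similarity
#' @param m non-negative scale factor for the annotation columns of the
#'   combined layout; `m = 0` reproduces the global layout exactly, large
#'   `m` approaches the functional layout.
#' @export
combined_features <- function(network, annotations, m = 1,
                              restart_prob = 0.2) {
  network <- assert_network(network, connected = TRUE)
  if (!is.numeric(m) || length(m) != 1 || !is.finite(m) || m < 0) {
    abort_input("`m` must be a non-negative finite number")
  }
  annotations <- as.matrix(annotations)
  if (nrow(annotations) != igraph::vcount(network)) {
    abort_input("`annotations` must have one row per network node")
  }
  if (!is.null(rownames(annotations)) &&
      !identical(rownames(annotations), node_ids(network))) {
    if (!setequal(rownames(annotations), node_ids(network))) {
      abort_input("`annotations` row names do not match the network's node identifiers")
    }
    annotations <- annotations[node_ids(network), , drop = FALSE]
  }
  p <- rwr_visiting_frequencies(network, restart_prob)
  feats <- cbind(p, m * annotations)
  rownames(feats) <- node_ids(network)
  feats
}

#' @rdname global_similarity
#' @export
combined_similarity <- function(network, annotations, m = 1,
                                restart_prob = 0.2) {
  cosine_similarity_matrix(
    combined_features(network, annotations, m = m, restart_prob = restart_prob),
    layout_kind = "combined")
}
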