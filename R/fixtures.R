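#' Synthetic block-structured annotations
#'
#' Generates a binary node-by-feature annotation matrix with planted group
#' structure, emulating how disease-gene annotations cluster in real data:
#' nodes fall into groups, each group owns a contiguous block of features,
#' group members are annotated to their own block with high probability and
#' to foreign features with a low background probability, and a fraction of
#' "pleiotropic" nodes is additionally annotated to a second, randomly
#' chosen group's block (the multi-disease genes that end up between
#' clusters in a functional layout).
#'
#' @param n_groups number of groups (default 4).
#' @param nodes_per_group nodes per group (default 25).
#' @param n_features total number of binary features; each group gets
#'   `n_features %/% n_groups` features, the remainder going to the last
#'   group. Default 20.
#' @param within_group_prob annotation probability inside a node's own
#'   block (default 0.9); must be at least `background_prob`.
#' @param background_prob annotation probability outside the block
#'   (default 0.01).
#' @param pleiotropy_fraction fraction of nodes annotated to a second
#'   group's block at `within_group_prob` (default 0).
#' @param seed integer seed; the matrix is reproducible from it.
#' @param node_ids optional node identifiers (row names); default
#'   `g<group>_n<index>`.
#' @return Binary matrix with one row per node, a `group` attribute holding
#'   each node's group index, and feature labels `f1, f2, ...`.
#' @examples
#' ann <- generate_block_annotations(within_group_prob = 1,
#'                                   background_prob = 0, seed = 1)
#' functional_similarity(ann)[1, 30]  # disjoint groups: 0
#' @export
generate_block_annotations <- function(n_groups = 4, nodes_per_group = 25,
                                       n_features = 20,
                                       within_group_prob = 0.9,
                                       background_prob = 0.01,
                                       pleiotropy_fraction = 0,
                                       seed = 1, node_ids = NULL) {
  for (nm in c("n_groups", "nodes_per_group", "n_features")) {
    v <- get(nm)
    if (!is.numeric(v) || v != round(v) || v < 1) {
      abort_input("`%s` must be a positive integer", nm)
    }
  }
  for (nm in c("within_group_prob", "background_prob", "pleiotropy_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort_input("`%s` must lie in [0, 1]", nm)
    }
  }
  if (within_group_prob < background_prob) {
    abort_input("`within_group_prob` must be >= `background_prob`")
  }
  if (n_features < n_groups) {
    abort_input("`n_features` must be at least `n_groups`")
  }
  n_nodes <- n_groups * nodes_per_group
  group <- rep(seq_len(n_groups), each = nodes_per_group)
  per_block <- n_features %/% n_groups
  block_start <- (seq_len(n_groups) - 1) * per_block + 1
  block_end <- c(block_start[-1] - 1, n_features)  # remainder to last group

  withr::with_seed(as.integer(seed), {
    mat <- matrix(
      as.integer(stats::runif(n_nodes * n_features) < background_prob),
      n_nodes, n_features)
    for (g in seq_len(n_groups)) {
      rows <- which(group == g)
      cols <- block_start[g]:block_end[g]
      mat[rows, cols] <- as.integer(
        stats::runif(length(rows) * length(cols)) < within_group_prob)
    }
    n_pleio <- round(pleiotropy_fraction * n_nodes)
    if (n_pleio > 0) {
      pleio <- sample(n_nodes, n_pleio)
      for (node in pleio) {
        other <- sample(setdiff(seq_len(n_groups), group[node]), 1)
        cols <- block_start[other]:block_end[other]
        mat[node, cols] <- as.integer(
          stats::runif(length(cols)) < within_group_prob)
      }
    }
  })
  rownames(mat) <- node_ids %||%
    sprintf("g%d_n%02d", group, seq_len(n_nodes) - (group - 1) * nodes_per_group)
  colnames(mat) <- sprintf("f%d", seq_len(n_features))
  attr(mat, "group") <- group
  mat
}

#' Per-node scalar variables
#'
#' Convenience generator for the extra per-node variable consumed by
#' topographic and geodesic maps: the node degree, a reproducible uniform
#' random value, or the number of annotations per node (the synthetic
#' analogue of "number of diseases associated with a gene").
#'
#' @inheritParams rwr_visiting_frequencies
#' @param kind `"degree"`, `"uniform-random"`, or `"annotation-count"`.
#' @param seed seed for `"uniform-random"` (default 1).
#' @param annotations binary annotation matrix, required for
#'   `"annotation-count"`; row sums are returned.
#' @return Named numeric vector, one finite value per node in network
#'   order.
#' @export
generate_node_scalar <- function(network,
                                 kind = c("degree", "uniform-random",
                                          "annotation-count"),
                                 seed = 1, annotations = NULL) {
  network <- assert_network(network)
  kind <- match.arg(kind)
  ids <- node_ids(network)
  values <- switch(kind,
    "degree" = as.numeric(igraph::degree(network)),
    "uniform-random" = withr::with_seed(as.integer(seed),
                                        stats::runif(length(ids))),
    "annotation-count" = {
      if (is.null(annotations)) {
        abort_input("`annotations` is required for kind = 'annotation-count'")
      }
      annotations <- as.matrix(annotations)
      if (!is.null(rownames(annotations))) {
        absent <- setdiff(ids, rownames(annotations))
        if (length(absent) > 0) {
          abort_input("`annotations` lacks rows for %d node(s), e.g. '%s'",
                      length(absent), absent[1])
        }
        annotations <- annotations[ids, , drop = FALSE]
      } else if (nrow(annotations) != length(ids)) {
        abort_input("`annotations` must have one row per network node")
      }
      rowSums(annotations)
    })
  stats::setNames(values, ids)
}
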