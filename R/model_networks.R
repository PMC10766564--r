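#' Benchmark model networks
#'
#' Deterministic generators for the three model networks used to illustrate
#' and benchmark the layout framework: a non-periodic cubic grid, a Cayley
#' tree and a periodic torus lattice. All three have fully understood
#' structure — canonical shapes, known degree sequences and, for the torus,
#' complete node equivalence — which makes them ideal yardsticks for judging
#' whether a layout reflects the network characteristics it claims to encode.
#'
#' Node identifiers encode the construction coordinates (lattice position or
#' `shell_index`) as underscore-separated strings, and vertices are ordered
#' by those numeric components, so regenerating a model with the same
#' parameters yields an identical graph, byte for byte.
#'
#' @param n_side edge length of the cubic grid; the grid has `n_side^3` nodes.
#' @return An undirected, simple [igraph::igraph] object with named vertices.
#' @examples
#' g <- generate_cubic_grid(3)
#' table(igraph::degree(g))  # corners 3, edge lines 4, faces 5, interior 6
#' @seealso [generate_cayley_tree()], [generate_torus_lattice()]
#' @export
generate_cubic_grid <- function(n_side) {
  if (!is.numeric(n_side) || length(n_side) != 1 || n_side != round(n_side) ||
      n_side < 2) {
    abort_input("`n_side` must be an integer >= 2")
  }
  n_side <- as.integer(n_side)
  coords <- expand.grid(z = 0:(n_side - 1), y = 0:(n_side - 1),
                        x = 0:(n_side - 1))
  coords <- coords[order(coords$x, coords$y, coords$z), c("x", "y", "z")]
  ids <- sprintf("%d_%d_%d", coords$x, coords$y, coords$z)
  idx <- function(x, y, z) x * n_side^2 + y * n_side + z + 1L

  from <- integer(0); to <- integer(0)
  for (axis in 1:3) {
    keep <- coords[[axis]] < n_side - 1
    nb <- coords[keep, , drop = FALSE]
    nb[[axis]] <- nb[[axis]] + 1L
    from <- c(from, idx(coords$x[keep], coords$y[keep], coords$z[keep]))
    to <- c(to, idx(nb$x, nb$y, nb$z))
  }
  g <- igraph::make_empty_graph(n = n_side^3, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::V(g)$name <- ids
  g$model <- "cubic_grid"
  g
}

#' @rdname generate_cubic_grid
#' @param coordination number of neighbours of every internal node (the
#'   root has `coordination` children; every other internal node has
#'   `coordination - 1` children plus its parent). The classic instance uses
#'   coordination 3.
#' @param levels number of shells around the root.
#' @examples
#' tree <- generate_cayley_tree(3, 2)
#' igraph::vcount(tree)  # 1 + 3 + 6 = 10
#' @export
generate_cayley_tree <- function(coordination = 3, levels = 7) {
  if (!is.numeric(coordination) || coordination != round(coordination) ||
      coordination < 2) {
    abort_input("`coordination` must be an integer >= 2")
  }
  if (!is.numeric(levels) || levels != round(levels) || levels < 1) {
    abort_input("`levels` must be an integer >= 1")
  }
  coordination <- as.integer(coordination); levels <- as.integer(levels)

  shell_size <- c(1L, coordination * (coordination - 1L)^(seq_len(levels) - 1L))
  offsets <- cumsum(c(0L, shell_size))  # index of first node in each shell
  n_total <- sum(shell_size)

  ids <- character(n_total)
  from <- integer(0); to <- integer(0)
  ids[1] <- "0_0"
  for (l in seq_len(levels)) {
    j <- seq_len(shell_size[l + 1]) - 1L
    ids[offsets[l + 1] + j + 1L] <- sprintf("%d_%d", l, j)
    parent_j <- if (l == 1) rep(0L, length(j)) else j %/% (coordination - 1L)
    from <- c(from, offsets[l] + parent_j + 1L)
    to <- c(to, offsets[l + 1] + j + 1L)
  }
  g <- igraph::make_empty_graph(n = n_total, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::V(g)$name <- ids
  g$model <- "cayley_tree"
  g
}

#' @rdname generate_cubic_grid
#' @param rows,cols dimensions of the torus lattice (both at least 3 so the
#'   wrap-around does not create duplicate edges). Every node has degree 4
#'   and all nodes are structurally equivalent.
#' @examples
#' torus <- generate_torus_lattice(3, 3)
#' unique(igraph::degree(torus))  # 4
#' @export
generate_torus_lattice <- function(rows, cols) {
  for (v in list(rows = rows, cols = cols)) {
    if (!is.numeric(v) || v != round(v) || v < 3) {
      abort_input("`rows` and `cols` must be integers >= 3")
    }
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  coords <- expand.grid(c = 0:(cols - 1), r = 0:(rows - 1))
  coords <- coords[order(coords$r, coords$c), c("r", "c")]
  ids <- sprintf("%d_%d", coords$r, coords$c)
  idx <- function(r, c) r * cols + c + 1L

  from <- c(idx(coords$r, coords$c), idx(coords$r, coords$c))
  to <- c(idx((coords$r + 1L) %% rows, coords$c),
          idx(coords$r, (coords$c + 1L) %% cols))
  g <- igraph::make_empty_graph(n = rows * cols, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::V(g)$name <- ids
  g$model <- "torus_lattice"
  g
}
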