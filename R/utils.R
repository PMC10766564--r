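`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
abort_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# min-max scale a vector to [0, 1]; a constant vector maps to 0.5 so that
# equal inputs stay equal (a torus column of identical centralities must not
# blow up to 0/0)
minmax_scale <- function(x, constant_value = 0.5) {
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    return(rep(constant_value, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Polynomial rolling hash (base 31, modulus 2^31 - 1) of a character vector,
# as an 8-digit hex string. Used only to stamp a short config fingerprint
# into provenance headers; all intermediates stay below 2^53 so the
# arithmetic is exact in doubles.
config_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Check that a network is a named, simple, undirected igraph object and
# return it with vertices in the package's canonical (construction) order.
assert_network <- function(network, connected = FALSE, arg = "network") {
  if (!igraph::is_igraph(network)) {
    abort_input("`%s` must be an igraph object", arg)
  }
  if (igraph::is_directed(network)) {
    abort_input("`%s` must be an undirected graph", arg)
  }
  if (is.null(igraph::V(network)$name)) {
    igraph::V(network)$name <- as.character(seq_len(igraph::vcount(network)))
  }
  if (any(igraph::which_loop(network)) || any(igraph::which_multiple(network))) {
    abort_input("`%s` must be a simple graph (no self-loops or duplicate edges)", arg)
  }
  if (connected && !igraph::is_connected(network)) {
    abort_input(paste(
      "`%s` is disconnected; restrict the analysis to its largest connected",
      "component first (e.g. largest_component())"), arg)
  }
  network
}

node_ids <- function(network) igraph::V(network)$name

# align a per-node vector (possibly named) to the network node order
align_scalar <- function(values, network, arg = "values") {
  ids <- node_ids(network)
  if (!is.null(names(values))) {
    missing <- setdiff(ids, names(values))
    if (length(missing) > 0) {
      abort_input("`%s` is missing values for %d node(s), e.g. '%s'",
                  arg, length(missing), missing[1])
    }
    values <- values[ids]
  } else if (length(values) != length(ids)) {
    abort_input("`%s` has length %d but the network has %d nodes",
                arg, length(values), length(ids))
  }
  if (!all(is.finite(values))) {
    abort_input("`%s` contains non-finite values", arg)
  }
  unname(values)
}
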