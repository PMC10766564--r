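#' Network maps (cartographs)
#'
#' An embedding becomes one of four map types:
#'
#' * **portrait (2D/3D)** — the embedded coordinates used directly as node
#'   positions ([make_portrait()]);
#' * **topographic** — a 2D portrait extended by a freely chosen per-node
#'   scalar as the z coordinate ([make_topographic()]);
#' * **geodesic** — nodes on concentric spherical layers
#'   ([make_geodesic()]), or on a sphere whose radius encodes a continuous
#'   per-node variable ([radial_geodesic()]).
#'
#' Every map records its provenance (layout kind, reducer, seed, geometry
#' and a configuration fingerprint) so a figure can be regenerated from its
#' metadata alone.
#'
#' @param embedding a `cartonet_embedding` (see [embed_similarity()]).
#' @return A list of class `cartonet_map` with elements `coordinates`
#'   (`N x 2` or `N x 3`, node identifiers as row names), `map_type`,
#'   optional `layer` and `scalar`, and `provenance`.
#' @name cartographs
NULL

new_map <- function(coordinates, map_type, embedding = NULL, layer = NULL,
                    scalar = NULL, layout_kind = NULL) {
  colnames(coordinates) <- c("x", "y", "z")[seq_len(ncol(coordinates))]
  prov <- list(
    layout_kind = layout_kind %||% embedding$layout_kind %||% "unspecified",
    method = embedding$method %||% "none",
    geometry = embedding$geometry %||% "none",
    seed = embedding$config$seed %||% NA_integer_)
  prov$config_hash <- config_hash(paste(
    prov$layout_kind, prov$method, prov$geometry, prov$seed, map_type))
  structure(list(coordinates = coordinates, map_type = map_type,
                 layer = layer, scalar = scalar, provenance = prov),
            class = "cartonet_map")
}

#' @rdname cartographs
#' @export
make_portrait <- function(embedding) {
  if (!inherits(embedding, "cartonet_embedding")) {
    abort_input("`embedding` must come from embed_similarity()")
  }
  if (embedding$geometry == "sphere") {
    abort_input(paste("portraits require plane2d or space3d geometry;",
                      "use make_geodesic() or radial_geodesic() for sphere embeddings"))
  }
  map_type <- if (embedding$geometry == "plane2d") "portrait2d" else "portrait3d"
  new_map(embedding$coordinates, map_type, embedding)
}

#' @rdname cartographs
#' @param z per-node scalar for the z axis (named by node identifier, or in
#'   network node order), e.g. the number of diseases associated with a
#'   gene. Min-max normalized, then scaled so the z range equals
#'   `z_scale` times the x-y bounding-box diagonal; a constant scalar
#'   collapses to the z = 0 plane.
#' @param z_scale z range as a fraction of the x-y bounding-box diagonal
#'   (default 0.25).
#' @export
make_topographic <- function(embedding, z, z_scale = 0.25) {
  if (!inherits(embedding, "cartonet_embedding")) {
    abort_input("`embedding` must come from embed_similarity()")
  }
  if (embedding$geometry != "plane2d") {
    abort_input("topographic maps extend a plane2d embedding")
  }
  xy <- embedding$coordinates
  if (!is.null(names(z))) {
    missing <- setdiff(rownames(xy), names(z))
    if (length(missing) > 0) {
      abort_input("`z` is missing values for %d node(s), e.g. '%s'",
                  length(missing), missing[1])
    }
    z <- z[rownames(xy)]
  }
  if (length(z) != nrow(xy)) {
    abort_input("`z` has length %d but the embedding has %d nodes",
                length(z), nrow(xy))
  }
  if (!all(is.finite(z))) abort_input("`z` contains non-finite values")
  bbox_diag <- sqrt(sum((apply(xy, 2, max) - apply(xy, 2, min))^2))
  znorm <- minmax_scale(unname(z), constant_value = 0)
  coords <- cbind(xy, z = znorm * z_scale * bbox_diag)
  new_map(coords, "topographic", embedding, scalar = unname(z))
}

#' @rdname cartographs
#' @param embeddings_per_layer list of sphere embeddings, one per layer
#'   (innermost first); layer `l`'s embedding must contain coordinates for
#'   every node assigned to layer `l`.
#' @param layer_assignment integer layer index per node, named by node
#'   identifier; each node belongs to exactly one layer.
#' @param radii strictly increasing positive radii, one per layer; default
#'   `1.0, 1.5, 2.0, ...`.
#' @export
make_geodesic <- function(embeddings_per_layer, layer_assignment,
                          radii = NULL) {
  n_layers <- length(embeddings_per_layer)
  if (n_layers < 1) abort_input("at least one layer embedding is required")
  for (e in embeddings_per_layer) {
    if (!inherits(e, "cartonet_embedding") || e$geometry != "sphere") {
      abort_input("every element of `embeddings_per_layer` must be a sphere embedding")
    }
  }
  radii <- radii %||% (1 + 0.5 * (seq_len(n_layers) - 1))
  if (length(radii) != n_layers || any(radii <= 0) || any(diff(radii) <= 0)) {
    abort_input("`radii` must be strictly increasing positive values, one per layer")
  }
  if (is.null(names(layer_assignment))) {
    abort_input("`layer_assignment` must be named by node identifier")
  }
  if (any(is.na(layer_assignment)) || any(!layer_assignment %in% seq_len(n_layers))) {
    abort_input("every node must be assigned to a layer in 1..%d", n_layers)
  }
  ids <- names(layer_assignment)
  coords <- matrix(NA_real_, length(ids), 3, dimnames = list(ids, NULL))
  for (l in seq_len(n_layers)) {
    members <- ids[layer_assignment == l]
    if (length(members) == 0) next
    sphere <- embeddings_per_layer[[l]]$coordinates
    absent <- setdiff(members, rownames(sphere))
    if (length(absent) > 0) {
      abort_input("layer %d embedding lacks coordinates for node '%s'", l, absent[1])
    }
    coords[members, ] <- radii[l] * sphere[members, , drop = FALSE]
  }
  first <- embeddings_per_layer[[1]]
  new_map(coords, "geodesic", first,
          layer = stats::setNames(as.integer(layer_assignment), ids))
}

#' @rdname cartographs
#' @param sphere_embedding a sphere-geometry embedding.
#' @param radial continuous per-node variable mapped to the radius
#'   `r0 + radial_scale * minmax(radial)`; angular positions are untouched.
#' @param r0 base radius (default 1).
#' @param radial_scale radial span added on top of `r0` (default 0.5).
#' @export
radial_geodesic <- function(sphere_embedding, radial, r0 = 1,
                            radial_scale = 0.5) {
  if (!inherits(sphere_embedding, "cartonet_embedding") ||
      sphere_embedding$geometry != "sphere") {
    abort_input("`sphere_embedding` must be a sphere embedding")
  }
  unit <- sphere_embedding$coordinates
  if (!is.null(names(radial))) radial <- radial[rownames(unit)]
  if (length(radial) != nrow(unit) || !all(is.finite(radial))) {
    abort_input("`radial` must hold one finite value per node")
  }
  radius <- r0 + radial_scale * minmax_scale(unname(radial), constant_value = 0)
  coords <- unit * radius
  new_map(coords, "geodesic", sphere_embedding, scalar = unname(radial))
}

#' @export
print.cartonet_map <- function(x, ...) {
  cat(sprintf("<cartonet_map> %s, %d nodes (layout kind: %s, reducer: %s, seed %s)\n",
              x$map_type, nrow(x$coordinates), x$provenance$layout_kind,
              x$provenance$method, x$provenance$seed))
  invisible(x)
}

#' @export
as.data.frame.cartonet_map <- function(x, ...) {
  df <- data.frame(node_id = rownames(x$coordinates), x$coordinates,
                   row.names = NULL, check.names = FALSE)
  if (!is.null(x$layer)) df$layer <- unname(x$layer[df$node_id])
  if (!is.null(x$scalar)) df$scalar <- x$scalar
  df
}
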