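#' Read an undirected network from an edge list
#'
#' Parses a two-column delimited text file (tab, comma or space separated;
#' auto-detected in that order) into a simple undirected graph. Lines
#' starting with `#` and blank lines are skipped. Self-loops and duplicate
#' edges (in either orientation) are dropped with a message reporting the
#' counts; vertices are sorted by identifier so the node order is stable
#' across runs regardless of file order.
#'
#' @param path path to the edge-list file.
#' @return A named, simple, undirected [igraph::igraph] object.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort_input("edge-list file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort_input("edge-list file is empty: %s", path)
  body <- lines[keep]
  line_no <- which(keep)

  sep <- detect_delimiter(body)
  parts <- strsplit(body, sep, perl = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad) > 0) {
    abort_input("malformed edge-list line %d: '%s'",
                line_no[bad[1]], lines[line_no[bad[1]]])
  }
  from <- vapply(parts, `[[`, "", 1)
  to <- vapply(parts, `[[`, "", 2)

  loops <- from == to
  if (any(loops)) {
    message(sprintf("read_edge_list: dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]
  }
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("read_edge_list: dropped %d duplicate edge(s)", sum(dup)))
    from <- from[!dup]; to <- to[!dup]
  }
  if (length(from) == 0) abort_input("edge-list file contains no usable edges: %s", path)

  ids <- sort(unique(c(from, to)))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  g <- igraph::add_edges(g, rbind(match(from, ids), match(to, ids)))
  g
}

detect_delimiter <- function(body) {
  probe <- utils::head(body, 50)
  for (sep in c("\t", ",", " +")) {
    n_fields <- vapply(strsplit(probe, sep, perl = TRUE), length, 1L)
    if (all(n_fields >= 2)) return(sep)
  }
  "\\s+"
}

#' @rdname read_edge_list
#' @param network graph to write.
#' @param sep field separator (default tab).
#' @export
write_edge_list <- function(network, path, sep = "\t") {
  network <- assert_network(network)
  el <- igraph::as_edgelist(network)
  writeLines(paste(el[, 1], el[, 2], sep = sep), path)
  invisible(path)
}

#' Read a binary annotation matrix aligned to a network
#'
#' Reads a delimited table (header row; first column node identifiers;
#' remaining columns binary features) and aligns its rows to the network's
#' node order. Network nodes absent from the file receive all-zero rows and
#' file rows for unknown nodes are ignored; both cases are reported via
#' `message()`. Any non-binary cell is an error naming its position.
#'
#' @param path path to the annotation table.
#' @param network the network whose node order the matrix must follow.
#' @return Binary matrix, one row per network node, in network node order.
#' @export
read_annotations <- function(path, network) {
  network <- assert_network(network)
  if (!file.exists(path)) abort_input("annotation file not found: %s", path)
  first <- readLines(path, n = 1)
  sep_chr <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep_chr,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  ids_file <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) abort_input("annotation columns must be numeric 0/1")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad) > 0) {
    r <- (bad[1] - 1) %% nrow(values) + 1
    c <- (bad[1] - 1) %/% nrow(values) + 1
    abort_input("non-binary annotation value %s at file row %d, column '%s'",
                format(values[bad[1]]), r, colnames(values)[c])
  }
  ids <- node_ids(network)
  unknown <- setdiff(ids_file, ids)
  if (length(unknown) > 0) {
    message(sprintf("read_annotations: ignored %d row(s) for nodes not in the network",
                    length(unknown)))
  }
  missing <- setdiff(ids, ids_file)
  if (length(missing) > 0) {
    message(sprintf("read_annotations: %d network node(s) without annotations get all-zero rows",
                    length(missing)))
  }
  out <- matrix(0L, length(ids), ncol(values),
                dimnames = list(ids, colnames(values)))
  keep <- ids_file %in% ids
  out[ids_file[keep], ] <- values[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_annotations
#' @param annotations binary matrix to write (row names are node ids).
#' @param id_column header label of the identifier column (default
#'   `"node_id"`).
#' @export
write_annotations <- function(annotations, path, id_column = "node_id") {
  df <- data.frame(rownames(annotations), annotations, check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a similarity matrix as delimited text
#'
#' @param similarity a similarity matrix with node identifiers as dimnames.
#' @param path output path.
#' @export
write_similarity_matrix <- function(similarity, path) {
  utils::write.table(as.matrix(similarity), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

provenance_lines <- function(map) {
  p <- map$provenance
  c(sprintf("# cartonet cartograph: map_type=%s layout_kind=%s method=%s geometry=%s seed=%s config_hash=%s",
            map$map_type, p$layout_kind, p$method, p$geometry, p$seed,
            p$config_hash))
}

#' Write a cartograph to CSV, GraphML or standalone HTML
#'
#' CSV holds one row per node (`node_id, x, y[, z][, layer][, scalar]`)
#' under a `#`-prefixed provenance header. GraphML attaches the coordinates
#' (and layer, if any) as node attributes of the supplied network. HTML is
#' a self-contained interactive viewer (inline data and script, no external
#' assets) that renders the map as a rotatable point cloud.
#'
#' @param cartograph a `cartonet_map`.
#' @param path output path.
#' @param format `"csv"`, `"graphml"` or `"html"`.
#' @param network required for `"graphml"`: the network whose edges the
#'   file should carry.
#' @return The path, invisibly.
#' @seealso [read_cartograph()] for the CSV round trip.
#' @export
write_cartograph <- function(cartograph, path,
                             format = c("csv", "graphml", "html"),
                             network = NULL) {
  if (!inherits(cartograph, "cartonet_map")) {
    abort_input("`cartograph` must be a cartonet_map")
  }
  format <- match.arg(format)
  switch(format,
    csv = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(provenance_lines(cartograph), con)
      utils::write.csv(as.data.frame(cartograph), con, row.names = FALSE,
                       quote = FALSE)
    },
    graphml = {
      if (is.null(network)) {
        abort_input("`network` is required for GraphML export")
      }
      network <- assert_network(network)
      coords <- cartograph$coordinates
      absent <- setdiff(node_ids(network), rownames(coords))
      if (length(absent) > 0) {
        abort_input("cartograph lacks coordinates for network node '%s'", absent[1])
      }
      coords <- coords[node_ids(network), , drop = FALSE]
      for (k in seq_len(ncol(coords))) {
        network <- igraph::set_vertex_attr(network, colnames(coords)[k],
                                           value = coords[, k])
      }
      if (!is.null(cartograph$layer)) {
        network <- igraph::set_vertex_attr(
          network, "layer", value = unname(cartograph$layer[node_ids(network)]))
      }
      network <- igraph::set_graph_attr(network, "cartonet_provenance",
                                        provenance_lines(cartograph))
      igraph::write_graph(network, path, format = "graphml")
    },
    html = write_cartograph_html(cartograph, path)
  )
  invisible(path)
}

#' @rdname write_cartograph
#' @export
read_cartograph <- function(path) {
  if (!file.exists(path)) abort_input("cartograph file not found: %s", path)
  header <- readLines(path, n = 1)
  prov <- list()
  if (startsWith(header, "#")) {
    for (kv in strsplit(sub("^#\\s*cartonet cartograph:\\s*", "", header), " ")[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2) prov[[parts[1]]] <- parts[2]
    }
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  coord_cols <- intersect(c("x", "y", "z"), names(df))
  coords <- as.matrix(df[, coord_cols, drop = FALSE])
  rownames(coords) <- df$node_id
  m <- new_map(coords, prov$map_type %||% "portrait2d",
               layer = if ("layer" %in% names(df))
                 stats::setNames(df$layer, df$node_id),
               scalar = if ("scalar" %in% names(df)) df$scalar,
               layout_kind = prov$layout_kind)
  m$provenance <- utils::modifyList(m$provenance, prov)
  m
}

# Minimal self-contained viewer: node coordinates inlined as JSON-ish JS,
# orthographic projection with mouse-drag rotation on a <canvas>.
write_cartograph_html <- function(map, path) {
  coords <- map$coordinates
  if (ncol(coords) == 2) coords <- cbind(coords, z = 0)
  scale <- max(abs(coords), 1e-12)
  pts <- apply(coords / scale, 1, function(r)
    sprintf("[%.5f,%.5f,%.5f]", r[1], r[2], r[3]))
  layer_js <- if (!is.null(map$layer)) {
    paste(unname(map$layer[rownames(map$coordinates)]), collapse = ",")
  } else paste(rep(0L, nrow(coords)), collapse = ",")
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>cartonet %s</title>", map$map_type),
    paste0("<!-- ", provenance_lines(map), " -->"),
    "<style>body{margin:0;background:#101018;color:#ddd;font:13px sans-serif}",
    "#info{position:fixed;top:8px;left:8px}</style></head><body>",
    sprintf("<div id=\"info\">%s &middot; %s layout &middot; drag to rotate</div>",
            map$map_type, map$provenance$layout_kind),
    "<canvas id=\"c\"></canvas><script>",
    paste0("const P=[", paste(pts, collapse = ","), "];"),
    paste0("const L=[", layer_js, "];"),
    "const cv=document.getElementById('c'),cx=cv.getContext('2d');",
    "let ax=0.5,ay=0.5,drag=false,px=0,py=0;",
    "function draw(){cv.width=innerWidth;cv.height=innerHeight;",
    "const s=0.35*Math.min(cv.width,cv.height);",
    "cx.fillStyle='#101018';cx.fillRect(0,0,cv.width,cv.height);",
    "const ca=Math.cos(ax),sa=Math.sin(ax),cb=Math.cos(ay),sb=Math.sin(ay);",
    "const cols=['#7fc8ff','#ffb366','#9ef29e','#f78fb3','#d9b3ff'];",
    "for(const[i,p]of P.entries()){",
    "const x=p[0]*cb+p[2]*sb,z0=-p[0]*sb+p[2]*cb;",
    "const y=p[1]*ca-z0*sa;",
    "cx.fillStyle=cols[L[i]%cols.length];",
    "cx.beginPath();cx.arc(cv.width/2+x*s,cv.height/2-y*s,2.2,0,6.3);cx.fill();}}",
    "cv.onmousedown=e=>{drag=true;px=e.clientX;py=e.clientY};",
    "onmouseup=()=>drag=false;",
    "onmousemove=e=>{if(drag){ay+=(e.clientX-px)*0.01;ax+=(e.clientY-py)*0.01;",
    "px=e.clientX;py=e.clientY;draw()}};",
    "onresize=draw;draw();",
    "</script></body></html>")
  writeLines(html, path)
  invisible(path)
}
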