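#' Build a multiplex network from an edge table
#'
#' A multiplex network is a set of layers over one shared node set; each
#' layer is an undirected, unweighted simple graph (symmetric binary
#' adjacency, zero diagonal). Interlayer couplings between a node and its
#' counterparts are implicit in the formalism and never materialized.
#'
#' @param edges A data frame with columns `layer`, `from`, `to` (one row per
#'   intra-layer edge; duplicates and symmetric repeats collapse to a single
#'   edge). An optional `weight` column is validated to be 1 everywhere.
#' @param nodes Optional character vector of node labels; the node set is the
#'   union of `nodes` and all endpoints, so isolated nodes can be declared.
#' @param layers Optional character vector fixing layer order (and allowing
#'   empty layers); defaults to order of first appearance.
#'
#' @return An object of class `multiplex_network`: node labels, layer labels
#'   and one dense symmetric 0/1 adjacency matrix per layer.
#' @export
#' @examples
#' net <- multiplex_network(
#'   tibble::tibble(layer = c("L1", "L2"), from = c("a", "b"), to = c("b", "c"))
#' )
#' net
multiplex_network <- function(edges, nodes = NULL, layers = NULL) {
  edges <- tibble::as_tibble(edges)
  req <- c("layer", "from", "to")
  if (!all(req %in% names(edges))) {
    rlang::abort("`edges` must have columns layer, from, to")
  }
  if ("weight" %in% names(edges) && nrow(edges) > 0) {
    w <- as.numeric(edges$weight)
    if (any(is.na(w)) || any(w != 1)) {
      rlang::abort("only unweighted networks are supported (all weights must be 1)",
                   class = "muxrec_weight_error")
    }
  }
  edges$layer <- as.character(edges$layer)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) {
    bad <- edges[edges$from == edges$to, ]
    rlang::abort(
      sprintf("self-loops are not allowed (e.g. %s: %s-%s)",
              bad$layer[1], bad$from[1], bad$to[1]),
      class = "muxrec_selfloop_error")
  }
  node_ids <- unique(c(nodes, edges$from, edges$to))
  if (length(node_ids) == 0) rlang::abort("network has no nodes")
  layer_ids <- layers %||% unique(edges$layer)
  if (!all(edges$layer %in% layer_ids)) {
    rlang::abort("`layers` must cover every layer present in `edges`")
  }
  n <- length(node_ids)
  adj <- lapply(layer_ids, function(l) {
    m <- matrix(0L, n, n, dimnames = list(node_ids, node_ids))
    e <- edges[edges$layer == l, ]
    if (nrow(e) > 0) {
      i <- match(e$from, node_ids)
      j <- match(e$to, node_ids)
      m[cbind(i, j)] <- 1L
      m[cbind(j, i)] <- 1L
    }
    m
  })
  names(adj) <- layer_ids
  structure(
    list(node_ids = node_ids, layer_ids = layer_ids, adj = adj),
    class = "multiplex_network")
}

#' Construct a multiplex network directly from adjacency matrices
#'
#' @param adj Named list of symmetric binary matrices sharing dimnames.
#' @param node_ids Node labels; defaults to rownames of the first matrix.
#' @return A `multiplex_network`.
#' @export
multiplex_from_adjacency <- function(adj, node_ids = NULL) {
  stopifnot(is.list(adj), length(adj) >= 1)
  node_ids <- node_ids %||% rownames(adj[[1]]) %||% as.character(seq_len(nrow(adj[[1]])))
  layer_ids <- names(adj) %||% paste0("L", seq_along(adj))
  n <- length(node_ids)
  adj <- lapply(adj, function(m) {
    m <- matrix(as.integer(m != 0), n, n, dimnames = list(node_ids, node_ids))
    m
  })
  names(adj) <- layer_ids
  net <- structure(
    list(node_ids = node_ids, layer_ids = layer_ids, adj = adj),
    class = "multiplex_network")
  validate_multiplex(net)
  net
}

validate_multiplex <- function(net) {
  for (l in net$layer_ids) {
    m <- net$adj[[l]]
    if (!isTRUE(all.equal(m, t(m)))) {
      rlang::abort(sprintf("layer %s adjacency is not symmetric", l))
    }
    if (any(diag(m) != 0)) {
      rlang::abort(sprintf("layer %s has self-loops", l),
                   class = "muxrec_selfloop_error")
    }
    if (!all(m %in% c(0L, 1L))) {
      rlang::abort(sprintf("layer %s adjacency is not binary", l))
    }
  }
  invisible(net)
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("<multiplex_network: %d nodes, %d layer%s>\n",
              n_nodes(x), n_layers(x), if (n_layers(x) == 1) "" else "s"))
  ec <- edge_counts(x)
  for (l in x$layer_ids) cat(sprintf("  %s: %d edges\n", l, ec[[l]]))
  invisible(x)
}

#' Number of nodes in the shared node set
#' @param net A `multiplex_network`.
#' @export
n_nodes <- function(net) length(net$node_ids)

#' Number of layers
#' @param net A `multiplex_network`.
#' @export
n_layers <- function(net) length(net$layer_ids)

#' Per-layer edge counts
#' @param net A `multiplex_network`.
#' @return Named integer vector, one entry per layer.
#' @export
edge_counts <- function(net) {
  vapply(net$adj, function(m) sum(m) %/% 2L, integer(1))
}

#' Adjacency matrix of one layer
#' @param net A `multiplex_network`.
#' @param layer Layer label.
#' @export
adjacency <- function(net, layer) {
  if (!layer %in% net$layer_ids) rlang::abort(sprintf("no layer '%s'", layer))
  net$adj[[layer]]
}

#' @importFrom tibble as_tibble
#' @method as_tibble multiplex_network
#' @export
as_tibble.multiplex_network <- function(x, ...) {
  rows <- purrr::map_dfr(x$layer_ids, function(l) {
    m <- x$adj[[l]]
    idx <- which(upper.tri(m) & m == 1L)
    if (length(idx) == 0) return(tibble::tibble(layer = character(),
                                                from = character(),
                                                to = character()))
    i <- ((idx - 1L) %% nrow(m)) + 1L
    j <- ((idx - 1L) %/% nrow(m)) + 1L
    # canonical order: endpoints sorted within an edge, edges sorted by labels
    a <- pmin(x$node_ids[i], x$node_ids[j])
    b <- pmax(x$node_ids[i], x$node_ids[j])
    tibble::tibble(layer = l, from = a, to = b)[order(a, b), ]
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(layer = character(), from = character(),
                           to = character())
  }
  rows
}

#' Read a multilayer edge list
#'
#' Format: whitespace-separated records `layerID nodeID nodeID [weight]`,
#' `#` comments, and an optional `[NODES]` section listing isolated node
#' labels (one per line) before or after the edge records. Weights, when
#' present, must equal 1.
#'
#' @param path File path or connection.
#' @return A `multiplex_network`.
#' @export
read_multiplex_edgelist <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  in_nodes <- FALSE
  nodes <- character()
  recs <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "") next
    if (toupper(ln) == "[NODES]") { in_nodes <- TRUE; next }
    if (toupper(ln) == "[EDGES]") { in_nodes <- FALSE; next }
    if (in_nodes) { nodes <- c(nodes, strsplit(ln, "\\s+")[[1]]); next }
    f <- strsplit(ln, "\\s+")[[1]]
    if (!length(f) %in% c(3L, 4L)) {
      rlang::abort(sprintf("line %d: expected 'layer node node [weight]', got '%s'",
                           k, lines[k]),
                   class = "muxrec_parse_error")
    }
    if (length(f) == 4L) {
      w <- suppressWarnings(as.numeric(f[4]))
      if (is.na(w) || w != 1) {
        rlang::abort(sprintf("line %d: unsupported weight '%s' (must be 1)", k, f[4]),
                     class = "muxrec_weight_error")
      }
    }
    recs[[length(recs) + 1L]] <- f[1:3]
  }
  edges <- if (length(recs)) {
    m <- do.call(rbind, recs)
    tibble::tibble(layer = m[, 1], from = m[, 2], to = m[, 3])
  } else {
    tibble::tibble(layer = character(), from = character(), to = character())
  }
  multiplex_network(edges, nodes = nodes)
}

#' Read one edge-list file per layer
#'
#' Each file holds two-column `nodeID nodeID` records; the layer label is
#' taken from the file name (or `names(paths)`).
#'
#' @param paths Character vector of file paths, optionally named by layer.
#' @return A `multiplex_network` on the union node set.
#' @export
read_multiplex_layers <- function(paths) {
  ids <- names(paths) %||% sub("\\.[^.]*$", "", basename(paths))
  edges <- purrr::map2_dfr(paths, ids, function(p, l) {
    lines <- sub("#.*$", "", readLines(p))
    lines <- trimws(lines)
    lines <- lines[lines != ""]
    if (!length(lines)) {
      return(tibble::tibble(layer = character(), from = character(), to = character()))
    }
    f <- do.call(rbind, strsplit(lines, "\\s+"))
    if (ncol(f) < 2) rlang::abort(sprintf("%s: expected two columns", p),
                                  class = "muxrec_parse_error")
    tibble::tibble(layer = l, from = f[, 1], to = f[, 2])
  })
  multiplex_network(edges, layers = ids)
}

#' Write a multilayer edge list
#'
#' Each undirected edge is written once, endpoints in sorted order; isolated
#' nodes go into a `[NODES]` section so that read/write round-trips.
#'
#' @param net A `multiplex_network`.
#' @param path File path or connection.
#' @export
write_multiplex_edgelist <- function(net, path) {
  edges <- as_tibble(net)
  touched <- unique(c(edges$from, edges$to))
  isolated <- setdiff(net$node_ids, touched)
  con <- if (inherits(path, "connection")) path else file(path, "w")
  if (!inherits(path, "connection")) on.exit(close(con))
  writeLines("# multilayer edge list: layer from to", con)
  if (length(isolated)) {
    writeLines(c("[NODES]", isolated, "[EDGES]"), con)
  }
  if (nrow(edges)) {
    writeLines(sprintf("%s %s %s", edges$layer, edges$from, edges$to), con)
  }
  invisible(net)
}
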