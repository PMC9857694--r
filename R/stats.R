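#' Per-layer descriptive statistics
#'
#' Computes, for each layer, the seven descriptors customarily reported for
#' multiplex data: node count, edge count, link density
#' \eqn{\rho = 2|E|/(|N|(|N|-1))}, mean degree \eqn{\langle d\rangle = 2|E|/|N|},
#' mean connected-component size, size of the greatest connected component,
#' and the coefficient of variation of component sizes (population standard
#' deviation over mean, so a single component gives exactly 0).
#'
#' @param net A `multiplex_network`.
#' @param layers Layers to report (default all).
#' @param nodes `"active"` counts only nodes incident to at least one edge of
#'   the layer (how per-layer statistics of published multiplex datasets are
#'   usually tabulated); `"all"` uses the full shared node set, with isolated
#'   nodes counting as size-1 components.
#' @return A tibble with one row per layer and columns `layer`, `n_nodes`,
#'   `n_edges`, `density`, `mean_degree`, `mean_cc_size`, `gcc_size`,
#'   `cov_cc_size`.
#' @export
#' @examples
#' net <- generate_multiplex(50, 2, degree = "poisson:3", overlap = 0.5, seed = 1)
#' layer_stats(net)
layer_stats <- function(net, layers = NULL, nodes = c("active", "all")) {
  nodes <- match.arg(nodes)
  layers <- layers %||% net$layer_ids
  purrr::map_dfr(layers, function(l) {
    m <- adjacency(net, l)
    deg <- rowSums(m)
    if (nodes == "active") {
      keep <- deg > 0
      if (!any(keep)) keep <- rep(TRUE, length(deg)) # edgeless layer: keep all
      m <- m[keep, keep, drop = FALSE]
    }
    nn <- nrow(m)
    ne <- sum(m) %/% 2L
    if (nn < 2) {
      rlang::abort(sprintf("layer %s: density undefined for fewer than 2 nodes", l),
                   class = "muxrec_domain_error")
    }
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
    cc <- igraph::components(g)$csize
    mu <- mean(cc)
    sd_pop <- sqrt(mean((cc - mu)^2))
    tibble::tibble(
      layer = l,
      n_nodes = nn,
      n_edges = ne,
      density = 2 * ne / (nn * (nn - 1)),
      mean_degree = 2 * ne / nn,
      mean_cc_size = mu,
      gcc_size = max(cc),
      cov_cc_size = sd_pop / mu)
  })
}

#' Check the no-giant-hub feasibility condition
#'
#' The exact degree update of the configuration-model M-step has a real
#' solution only when no node is incident to more than half of a layer's
#' edges, i.e. \eqn{d_i \le |E^\ell|} for every node. Sparse multiplex data
#' typically satisfy this comfortably.
#'
#' @param net A `multiplex_network`.
#' @return A tibble with columns `layer`, `n_edges`, `max_degree`, `passes`,
#'   and a list-column `violators` of offending node labels.
#' @export
check_hub_condition <- function(net) {
  purrr::map_dfr(net$layer_ids, function(l) {
    m <- adjacency(net, l)
    deg <- rowSums(m)
    e <- sum(deg) / 2
    bad <- net$node_ids[deg > e]
    tibble::tibble(
      layer = l,
      n_edges = as.integer(e),
      max_degree = as.integer(max(deg)),
      passes = length(bad) == 0,
      violators = list(bad))
  })
}
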