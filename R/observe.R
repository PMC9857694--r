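#' Partially observe a multiplex network by hiding nodes
#'
#' The observation model is node-level: in every layer a subset of nodes is
#' observed and a pair (i, j) is observed there iff both endpoints are.
#' Links incident to a hidden node are unobserved, which makes this a
#' network-reconstruction (not plain link-prediction) setting. Unobserved
#' adjacency entries are stored as `NA`, never as 0.
#'
#' @param net A `multiplex_network` (the ground truth).
#' @param fraction Observed node fraction `c` in \[0, 1\]; the subset size is
#'   `round(c * |N|)` (half-up).
#' @param shared_across_layers If `TRUE`, one node subset is drawn and reused
#'   in every layer; the default draws an independent subset per layer, the
#'   regime in which cross-layer evidence exists and the aggregation step
#'   pays off.
#' @param seed Optional integer seed; the same seed reproduces the masks.
#' @param observed_nodes Optional named list (layer -> node labels) that
#'   fixes the observed sets explicitly, overriding `fraction`.
#' @return An object of class `partial_observation` with per-layer observed
#'   node sets, the observed-pair masks, and the masked adjacencies `X`.
#' @export
#' @examples
#' net <- generate_multiplex(30, 2, degree = "poisson:3", overlap = 0.7, seed = 1)
#' obs <- mask_nodes(net, 0.6, seed = 2)
#' obs
mask_nodes <- function(net, fraction = NULL, shared_across_layers = FALSE,
                       seed = NULL, observed_nodes = NULL) {
  n <- n_nodes(net)
  ids <- net$node_ids
  if (is.null(observed_nodes)) {
    if (is.null(fraction) || fraction < 0 || fraction > 1) {
      rlang::abort("`fraction` must lie in [0, 1]", class = "muxrec_domain_error")
    }
    k <- as.integer(floor(fraction * n + 0.5))
    observed_nodes <- with_seed_opt(seed, {
      if (shared_across_layers) {
        s <- sample(ids, k)
        stats::setNames(rep(list(s), n_layers(net)), net$layer_ids)
      } else {
        stats::setNames(lapply(net$layer_ids, function(l) sample(ids, k)),
                        net$layer_ids)
      }
    })
  } else {
    if (!all(net$layer_ids %in% names(observed_nodes))) {
      rlang::abort("`observed_nodes` must name every layer")
    }
    observed_nodes <- lapply(observed_nodes[net$layer_ids], function(v) {
      if (!all(v %in% ids)) rlang::abort("observed node label not in network")
      as.character(v)
    })
    fraction <- NA_real_
  }
  mask <- lapply(net$layer_ids, function(l) {
    inset <- ids %in% observed_nodes[[l]]
    m <- outer(inset, inset, `&`)
    diag(m) <- FALSE
    dimnames(m) <- list(ids, ids)
    m
  })
  names(mask) <- net$layer_ids
  X <- lapply(net$layer_ids, function(l) {
    x <- net$adj[[l]]
    storage.mode(x) <- "double"
    x[!mask[[l]]] <- NA_real_
    diag(x) <- 0
    x
  })
  names(X) <- net$layer_ids
  structure(
    list(node_ids = ids, layer_ids = net$layer_ids,
         observed_nodes = observed_nodes,
         fraction = fraction, shared_across_layers = shared_across_layers,
         mask = mask, X = X, seed = seed),
    class = "partial_observation")
}

#' @export
print.partial_observation <- function(x, ...) {
  cat(sprintf("<partial_observation: %d nodes, %d layers%s>\n",
              length(x$node_ids), length(x$layer_ids),
              if (is.na(x$fraction %||% NA)) ""
              else sprintf(", nominal fraction %.2f", x$fraction)))
  for (l in x$layer_ids) {
    cat(sprintf("  %s: %d observed nodes, %d observed pairs\n",
                l, length(x$observed_nodes[[l]]),
                sum(x$mask[[l]][upper.tri(x$mask[[l]])])))
  }
  invisible(x)
}

#' Mask of unobserved (candidate) pairs of one layer
#'
#' The complement of the observed-pair set over i<j pairs. This set is both
#' the candidate pool of the random baseline and the domain over which
#' reconstructions are scored: pairs among observed nodes are never
#' predicted or evaluated.
#'
#' @param obs A `partial_observation`.
#' @param layer Layer label.
#' @return Logical matrix, `TRUE` exactly on unobserved i<j pairs.
#' @export
unobserved_pair_mask <- function(obs, layer) {
  m <- obs$mask[[layer]]
  if (is.null(m)) rlang::abort(sprintf("no layer '%s'", layer))
  !m & upper.tri(m)
}

#' Read an observation specification file
#'
#' YAML with either `fraction` (plus optional `seed`, `shared_layers`) or an
#' `observed_nodes` mapping of layer label to node-label list.
#'
#' @param path YAML file path.
#' @param net The `multiplex_network` the spec applies to.
#' @return A `partial_observation`.
#' @export
read_observation_spec <- function(path, net) {
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$observed_nodes)) {
    mask_nodes(net, observed_nodes = spec$observed_nodes)
  } else if (!is.null(spec$fraction)) {
    mask_nodes(net, fraction = spec$fraction,
               shared_across_layers = isTRUE(spec$shared_layers),
               seed = spec$seed)
  } else {
    rlang::abort("observation spec needs `fraction` or `observed_nodes`")
  }
}

#' Write an observation specification file
#' @param obs A `partial_observation`.
#' @param path Output YAML path.
#' @export
write_observation_spec <- function(obs, path) {
  yaml::write_yaml(list(observed_nodes = obs$observed_nodes), path)
  invisible(obs)
}
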