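#' Erased configuration-model layer
#'
#' Stub matching on the requested degree sequence followed by removal of
#' self-loops and multi-edges, so the result is always a simple graph and
#' realized degrees never exceed the requested ones (the small systematic
#' loss is O(1/n) for sparse sequences). An odd degree sum is fixed by
#' incrementing one random node.
#'
#' @param degrees Nonnegative integer degree sequence; each entry must be
#'   at most `length(degrees) - 1`.
#' @param seed Optional seed.
#' @return Symmetric binary adjacency matrix.
#' @export
configuration_layer <- function(degrees, seed = NULL) {
  degrees <- as.integer(degrees)
  n <- length(degrees)
  if (any(degrees < 0)) rlang::abort("degrees must be nonnegative",
                                     class = "muxrec_domain_error")
  if (any(degrees > n - 1)) rlang::abort("a degree exceeds n - 1",
                                         class = "muxrec_domain_error")
  with_seed_opt(seed, {
    if (sum(degrees) %% 2 == 1) {
      bump <- sample(which(degrees < n - 1), 1)
      degrees[bump] <- degrees[bump] + 1L
    }
    g <- if (sum(degrees) == 0) {
      igraph::make_empty_graph(n, directed = FALSE)
    } else {
      igraph::simplify(igraph::sample_degseq(degrees, method = "configuration"))
    }
    m <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    storage.mode(m) <- "integer"
    m
  })
}

parse_degree_model <- function(degree, n) {
  if (is.numeric(degree) && length(degree) == n) {
    return(list(draw = function() as.integer(degree), label = "explicit"))
  }
  if (!is.character(degree) || length(degree) != 1) {
    rlang::abort("`degree` must be a length-n sequence, 'poisson:<lambda>' or 'powerlaw:<exponent>:<dmax>'")
  }
  f <- strsplit(degree, ":")[[1]]
  if (f[1] == "poisson") {
    lambda <- as.numeric(f[2])
    if (is.na(lambda) || lambda <= 0) rlang::abort("poisson needs lambda > 0")
    list(draw = function() pmin(stats::rpois(n, lambda), n - 1L), label = degree)
  } else if (f[1] == "powerlaw") {
    gamma <- as.numeric(f[2])
    dmax <- min(if (length(f) >= 3) as.integer(f[3]) else n - 1L, n - 1L)
    if (is.na(gamma) || gamma <= 1) rlang::abort("powerlaw needs exponent > 1")
    supp <- seq_len(dmax)
    prob <- supp^(-gamma)
    list(draw = function() sample(supp, n, replace = TRUE, prob = prob),
         label = degree)
  } else {
    rlang::abort(sprintf("unknown degree model '%s'", f[1]))
  }
}

#' Generate a synthetic multiplex network with interlayer dependency
#'
#' Emulates the sparse multiplex regimes the reconstruction problem targets:
#' per-layer configuration-model topology with a prescribed degree
#' distribution, and a tunable fraction `overlap` of each layer's edges
#' drawn from a shared backbone. The backbone is one configuration-model
#' draw; every layer keeps each backbone edge independently with probability
#' `overlap` and supplements it with an independent configuration draw whose
#' degrees are a binomial (1 - overlap)-thinning of the layer's degree model
#' (for a Poisson model this thinning is exact). `overlap = 0` gives fully
#' independent layers; `overlap = 1` gives identical layers. Interlayer
#' dependence is exactly what the aggregation step of [run_ema()] exploits.
#'
#' @param n_nodes Number of nodes.
#' @param n_layers Number of layers.
#' @param degree Degree model: `"poisson:<lambda>"`,
#'   `"powerlaw:<exponent>:<dmax>"`, or an explicit integer sequence of
#'   length `n_nodes`.
#' @param overlap Backbone retention probability in \[0, 1\].
#' @param seed Optional seed; the same seed reproduces the multiplex.
#' @return A `multiplex_network` with a `provenance` attribute recording the
#'   spec, realized per-layer mean degrees, and the realized pairwise edge
#'   Jaccard between layers.
#' @export
#' @examples
#' net <- generate_multiplex(100, 2, degree = "poisson:3", overlap = 0.7, seed = 1)
#' attr(net, "provenance")$jaccard
generate_multiplex <- function(n_nodes, n_layers, degree = "poisson:3",
                               overlap = 0.7, seed = NULL) {
  if (overlap < 0 || overlap > 1) rlang::abort("`overlap` must lie in [0, 1]",
                                               class = "muxrec_domain_error")
  stopifnot(n_nodes >= 2, n_layers >= 1)
  model <- parse_degree_model(degree, n_nodes)
  ids <- as.character(seq_len(n_nodes))
  net <- with_seed_opt(seed, {
    backbone <- configuration_layer(model$draw())
    adj <- lapply(seq_len(n_layers), function(l) {
      keep <- backbone
      bidx <- which(upper.tri(keep) & keep == 1L)
      drop <- bidx[stats::runif(length(bidx)) > overlap]
      keep[drop] <- 0L
      keep <- symmetrize_upper(keep)
      diag(keep) <- 0L
      supp_deg <- stats::rbinom(n_nodes, model$draw(), 1 - overlap)
      supp <- configuration_layer(pmin(supp_deg, n_nodes - 1L))
      m <- pmax(keep, supp)
      dimnames(m) <- list(ids, ids)
      m
    })
    names(adj) <- paste0("L", seq_len(n_layers))
    multiplex_from_adjacency(adj, node_ids = ids)
  })
  jac <- matrix(1, n_layers, n_layers,
                dimnames = list(net$layer_ids, net$layer_ids))
  if (n_layers > 1) {
    for (a in 1:(n_layers - 1)) for (b in (a + 1):n_layers) {
      ea <- net$adj[[a]][upper.tri(net$adj[[a]])] == 1
      eb <- net$adj[[b]][upper.tri(net$adj[[b]])] == 1
      u <- sum(ea | eb)
      jac[a, b] <- jac[b, a] <- if (u == 0) NA_real_ else sum(ea & eb) / u
    }
  }
  attr(net, "provenance") <- list(
    n_nodes = n_nodes, n_layers = n_layers, degree = model$label,
    overlap = overlap, seed = seed,
    mean_degree = vapply(net$adj, function(m) mean(rowSums(m)), numeric(1)),
    jaccard = jac)
  net
}
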