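#' Solver configuration
#'
#' @param tolerance Convergence tolerance on the mean absolute change of the
#'   unobserved link probabilities between consecutive iterations
#'   (default `1e-5`).
#' @param max_iterations Iteration cap (default 100).
#' @param m_step `"approx"` uses the large-|E| degree update
#'   \eqn{d_i = \sum_j p_{ij}}; `"exact"` solves the configuration-model
#'   fixed point quadratic (see [solve_degree()]), falling back to the
#'   approximate update is the caller's choice on infeasibility.
#' @param a_step `"evidence"` (default) applies the aggregation Bayes update
#'   only to pairs where some layer observed a link; `"all_pairs"` applies it
#'   to every unobserved pair; `"off"` disables aggregation, giving the plain
#'   EM solver.
#' @param edge_count How the per-layer edge count |E| entering the
#'   configuration-model probability is handled. `"anchor"` (default) fixes
#'   it at an inverse-probability estimate from the observed subgraph,
#'   \eqn{\hat E = E_{obs} \cdot n(n-1)/(k(k-1))} with k observed nodes, and
#'   constrains the approximate M-step to \eqn{\sum_i d_i = 2\hat E}; the
#'   degree scale is then identified and the iteration contracts
#'   geometrically. `"estimate"` maintains the fully self-consistent
#'   \eqn{|E| = \sum_i d_i / 2}; it needs no anchor but has a quasi-neutral
#'   scale mode that converges very slowly and can settle far from the true
#'   count (see the methods vignette). `"known"` uses caller-supplied true
#'   counts, the same oracle the random baseline is granted. A layer with
#'   fewer than two observed nodes falls back from `"anchor"` to
#'   `"estimate"` (nothing to anchor on).
#' @param known_edge_counts Numeric vector of per-layer edge counts (in
#'   layer order, or named by layer), required for `edge_count = "known"`.
#' @param seed Optional seed for the random initialization.
#' @return An `ema_config` list.
#' @export
ema_config <- function(tolerance = 1e-5, max_iterations = 100,
                       m_step = c("approx", "exact"),
                       a_step = c("evidence", "off", "all_pairs"),
                       edge_count = c("anchor", "estimate", "known"),
                       known_edge_counts = NULL,
                       seed = NULL) {
  stopifnot(tolerance > 0, max_iterations >= 1)
  edge_count <- match.arg(edge_count)
  if (edge_count == "known" && is.null(known_edge_counts)) {
    rlang::abort("edge_count = \"known\" needs `known_edge_counts`")
  }
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 m_step = match.arg(m_step),
                 a_step = match.arg(a_step),
                 edge_count = edge_count,
                 known_edge_counts = known_edge_counts,
                 seed = seed),
            class = "ema_config")
}

# fixed per-layer edge counts (NA = self-consistent), per the config
fixed_edge_counts <- function(obs, cfg) {
  layers <- obs$layer_ids
  n <- length(obs$node_ids)
  out <- rep(NA_real_, length(layers))
  names(out) <- layers
  if (cfg$edge_count == "known") {
    k <- cfg$known_edge_counts
    if (!is.null(names(k))) k <- k[layers]
    if (length(k) != length(layers) || any(is.na(k))) {
      rlang::abort("`known_edge_counts` must give one count per layer")
    }
    out[] <- as.numeric(k)
  } else if (cfg$edge_count == "anchor") {
    for (l in layers) {
      k <- length(obs$observed_nodes[[l]])
      if (k >= 2) {
        e_obs <- sum(obs$X[[l]][obs$mask[[l]]]) / 2
        out[[l]] <- max(1, e_obs * n * (n - 1) / (k * (k - 1)))
      }
    }
  }
  out
}

#' Initialize the reconstruction state
#'
#' Degrees start at \eqn{d_i \sim U(1, |N|)} and unobserved link
#' probabilities at \eqn{U(0, 1)} (drawn on i<j and mirrored); observed
#' entries are clamped to the observation and stay clamped at every
#' iteration. The aggregate-evidence matrix A records, per pair, whether any
#' layer observed a link (1), every layer observed its absence (0), or
#' neither (unknown, `NA`).
#'
#' @param obs A `partial_observation`.
#' @param cfg An [ema_config()].
#' @return A `recon_state` list with elements `p`, `prior_p`, `d`,
#'   `edge_count_est`, `A`, `iteration`, `last_error`.
#' @export
init_state <- function(obs, cfg = ema_config()) {
  n <- length(obs$node_ids)
  if (n < 2) rlang::abort("need at least 2 nodes", class = "muxrec_domain_error")
  layers <- obs$layer_ids
  up <- upper_mask(n)
  state <- with_seed_opt(cfg$seed, {
    d <- lapply(layers, function(l) stats::runif(n, 1, n))
    p <- lapply(layers, function(l) {
      m <- matrix(0, n, n, dimnames = list(obs$node_ids, obs$node_ids))
      m[up] <- stats::runif(sum(up))
      m <- symmetrize_upper(m)
      msk <- obs$mask[[l]]
      m[msk] <- obs$X[[l]][msk]
      diag(m) <- 0
      m
    })
    list(d = d, p = p)
  })
  names(state$d) <- names(state$p) <- layers
  fixedE <- fixed_edge_counts(obs, cfg)
  A <- matrix(NA_real_, n, n, dimnames = list(obs$node_ids, obs$node_ids))
  pos <- Reduce(`|`, lapply(layers, function(l) obs$mask[[l]] & obs$X[[l]] == 1))
  allzero <- Reduce(`&`, lapply(layers, function(l) obs$mask[[l]] & obs$X[[l]] == 0))
  A[allzero] <- 0
  A[pos] <- 1
  diag(A) <- 0
  est <- vapply(state$d, function(x) sum(x) / 2, numeric(1))
  structure(
    list(p = state$p, prior_p = NULL, d = state$d,
         edge_count_est = ifelse(is.na(fixedE), est, fixedE),
         fixed_edge_count = fixedE,
         A = A, iteration = 0L, last_error = NA_real_),
    class = "recon_state")
}

#' Expectation step: configuration-model link probabilities
#'
#' For every unobserved pair the link probability becomes
#' \eqn{\min(1, d_i d_j / (2|E| - 1))} with the layer's current degree
#' estimates and edge-count estimate; observed pairs stay clamped to the
#' observation. The un-clamped, capped model value is retained for all pairs
#' (`prior_p`) because the aggregation step needs genuine model priors in
#' its denominator.
#'
#' @param state A `recon_state`.
#' @param obs The `partial_observation`.
#' @return The updated state.
#' @export
e_step <- function(state, obs) {
  for (l in obs$layer_ids) {
    e2 <- 2 * state$edge_count_est[[l]] - 1
    if (e2 <= 0) {
      rlang::abort(sprintf("layer %s: degenerate edge-count estimate (%g)",
                           l, state$edge_count_est[[l]]),
                   class = "muxrec_degenerate_layer")
    }
    d <- state$d[[l]]
    P <- pmin(outer(d, d) / e2, 1)
    diag(P) <- 0
    dimnames(P) <- dimnames(state$p[[l]])
    state$prior_p[[l]] <- P
    msk <- obs$mask[[l]]
    P[msk] <- obs$X[[l]][msk]
    state$p[[l]] <- P
  }
  state
}

#' Aggregation step: interlayer OR-evidence Bayes update
#'
#' A pair linked in at least one layer is linked in the OR-aggregate
#' topology. Conditioning a layer's prior on that aggregate evidence gives
#' the update \eqn{p^\ell \leftarrow \min(1,\; p^\ell / (1 - \prod_h (1 -
#' p^h)))} over layers h, which never decreases the probability. In
#' `"evidence"` mode the update applies only where some layer actually
#' observed a link; `"all_pairs"` applies it everywhere unobserved. A zero
#' denominator (all priors zero) leaves the entry untouched, observed
#' entries never change, and with a single layer the step is a no-op.
#'
#' @param state A `recon_state` whose `prior_p` is current (run [e_step()]
#'   first).
#' @param obs The `partial_observation`.
#' @param mode One of `"evidence"`, `"all_pairs"`, `"off"`.
#' @return The updated state.
#' @export
a_step <- function(state, obs, mode = c("evidence", "all_pairs", "off")) {
  mode <- match.arg(mode)
  if (mode == "off" || length(obs$layer_ids) < 2) return(state)
  if (is.null(state$prior_p)) rlang::abort("run e_step before a_step")
  denom <- 1 - Reduce(`*`, lapply(state$prior_p, function(P) 1 - P))
  for (l in obs$layer_ids) {
    sel <- !obs$mask[[l]] & denom > 0
    if (mode == "evidence") sel <- sel & !is.na(state$A) & state$A == 1
    diag(sel) <- FALSE
    upd <- pmin(1, state$prior_p[[l]][sel] / denom[sel])
    state$p[[l]][sel] <- upd
  }
  state
}

#' Exact configuration-model degree from a probability row sum
#'
#' Solves the stationarity condition \eqn{d (2|E| - d) = (2|E| - 1) s} for
#' the degree, where \eqn{s = \sum_j p_{ij}}: the smaller quadratic root
#' \eqn{d = |E| - \sqrt{|E|^2 - 2|E| s + s}} (the larger root exceeds the
#' number of links and is discarded). A real solution exists iff no node
#' carries more than half of the layer's edge ends, the no-giant-hub
#' condition of [check_hub_condition()]. For \eqn{|E| \gg d} the root
#' approaches \eqn{s} itself, which is the approximate M-step.
#'
#' @param strength Vector of probability row sums \eqn{s_i}.
#' @param n_edges The layer's edge-count estimate |E|.
#' @return Degree vector of the same length as `strength`.
#' @export
#' @examples
#' solve_degree(3, 10) # 10 - sqrt(43)
solve_degree <- function(strength, n_edges) {
  disc <- n_edges^2 - 2 * n_edges * strength + strength
  if (any(disc < 0)) {
    bad <- which(disc < 0)
    rlang::abort(
      sprintf("no real degree solution at position(s) %s: giant-hub condition violated",
              paste(utils::head(bad, 5), collapse = ", ")),
      class = "muxrec_infeasible", data = list(which = bad))
  }
  # conjugate form of |E| - sqrt(disc): avoids cancellation when s << |E|
  strength * (2 * n_edges - 1) / (n_edges + sqrt(disc))
}

#' Maximization step, approximate form
#'
#' Degree estimates become the probability row sums, \eqn{d_i = \sum_j
#' p_{ij}}, the large-|E| limit of the exact update. For a layer whose edge
#' count is anchored or known (see [ema_config()]), the update is
#' additionally normalized so that \eqn{\sum_i d_i = 2|E|} — the
#' maximization under the fixed-edge-count constraint — and the edge-count
#' estimate stays fixed; otherwise the estimate is kept self-consistent as
#' \eqn{\sum_i d_i / 2}.
#'
#' @param state A `recon_state`.
#' @return The updated state.
#' @export
m_step_approx <- function(state) {
  for (l in names(state$p)) {
    s <- rowSums(state$p[[l]])
    fx <- state$fixed_edge_count[[l]]
    if (!is.na(fx) && sum(s) > 0) {
      state$d[[l]] <- s * (2 * fx / sum(s))
      state$edge_count_est[[l]] <- fx
    } else {
      state$d[[l]] <- s
      state$edge_count_est[[l]] <- sum(s) / 2
    }
  }
  state
}

#' Maximization step, exact form
#'
#' Applies [solve_degree()] per node with the layer's current edge-count
#' estimate, then recomputes the edge-count estimate from the new degrees.
#' Signals a `muxrec_infeasible` error (naming the nodes) when the
#' no-giant-hub condition fails; callers may fall back to [m_step_approx()].
#'
#' @param state A `recon_state`.
#' @return The updated state.
#' @export
m_step_exact <- function(state) {
  for (l in names(state$p)) {
    s <- rowSums(state$p[[l]])
    state$d[[l]] <- tryCatch(
      solve_degree(s, state$edge_count_est[[l]]),
      muxrec_infeasible = function(e) {
        rlang::abort(
          sprintf("layer %s: %s", l, conditionMessage(e)),
          class = "muxrec_infeasible", parent = e)
      })
    fx <- state$fixed_edge_count[[l]]
    state$edge_count_est[[l]] <- if (!is.na(fx)) fx else sum(state$d[[l]]) / 2
  }
  state
}

#' Mean absolute change of the unobserved probabilities
#'
#' The convergence criterion: the mean, over all unobserved i<j pairs of all
#' layers, of the absolute difference between consecutive probability
#' estimates. With nothing unobserved the result is 0 (already converged).
#'
#' @param p_prev,p_curr Lists of per-layer probability matrices.
#' @param obs The `partial_observation` defining the unobserved pairs.
#' @return A nonnegative scalar.
#' @export
convergence_error <- function(p_prev, p_curr, obs) {
  tot <- 0
  cnt <- 0
  for (l in obs$layer_ids) {
    sel <- unobserved_pair_mask(obs, l)
    tot <- tot + sum(abs(p_curr[[l]][sel] - p_prev[[l]][sel]))
    cnt <- cnt + sum(sel)
  }
  if (cnt == 0) 0 else tot / cnt
}

#' Reconstruct a multiplex network from partial observations
#'
#' Iterates expectation, aggregation, and maximization steps until the mean
#' absolute change of the unobserved link probabilities falls below the
#' tolerance or the iteration cap is hit. With `a_step = "off"` (or a single
#' layer) this is the classical EM solver; the default is the aggregation-
#' augmented solver that exploits interlayer dependence.
#'
#' @param obs A `partial_observation`.
#' @param config An [ema_config()].
#' @return An `ema_fit`: per-layer probability matrices `p`, degree
#'   estimates `d`, edge-count estimates, the iteration trace of
#'   convergence errors, a `converged` flag, and the inputs' shape. Use
#'   [tidy.ema_fit()], [glance.ema_fit()], [autoplot.ema_fit()], and
#'   [evaluate_reconstruction()] on it. Non-convergence is flagged, not an
#'   error.
#' @export
#' @examples
#' net <- generate_multiplex(60, 2, degree = "poisson:3", overlap = 0.7, seed = 1)
#' obs <- mask_nodes(net, 0.5, seed = 2)
#' fit <- run_ema(obs, ema_config(seed = 3))
#' glance(fit)
run_ema <- function(obs, config = ema_config()) {
  state <- init_state(obs, config)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    p_prev <- state$p
    state <- e_step(state, obs)
    state <- a_step(state, obs, mode = config$a_step)
    state <- if (config$m_step == "exact") m_step_exact(state) else m_step_approx(state)
    err <- convergence_error(p_prev, state$p, obs)
    trace[it] <- err
    state$iteration <- it
    state$last_error <- err
    if (err <= config$tolerance) { converged <- TRUE; break }
  }
  structure(
    list(p = state$p, d = state$d, edge_count_est = state$edge_count_est,
         A = state$A, iterations = state$iteration, trace = trace,
         converged = converged, config = config, obs = obs,
         node_ids = obs$node_ids, layer_ids = obs$layer_ids),
    class = "ema_fit")
}

#' @export
print.ema_fit <- function(x, ...) {
  cat(sprintf("<ema_fit: %d nodes, %d layers, %s after %d iteration%s (MAE %.3g)>\n",
              length(x$node_ids), length(x$layer_ids),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, if (x$iterations == 1) "" else "s",
              x$trace[length(x$trace)]))
  invisible(x)
}
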