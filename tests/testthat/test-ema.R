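# ---- single-step arithmetic -------------------------------------------------

test_that("expectation step computes capped configuration-model probabilities", {
  net <- multiplex_network(tibble::tibble(layer = "L1", from = "n1", to = "n2"),
                           nodes = c("n3", "n4"))
  obs <- mask_nodes(net, 0, seed = 1) # everything unobserved
  st <- blank_state(obs)
  st$d$L1 <- c(3, 4, 0, 5)
  st$fixed_edge_count[] <- NA_real_
  st$edge_count_est[["L1"]] <- 10
  st <- e_step(st, obs)
  expect_equal(st$p$L1[1, 2], 12 / 19) # d_i d_j / (2|E| - 1)
  expect_equal(st$p$L1[1, 3], 0)       # zero-degree node
  expect_equal(st$prior_p$L1, t(st$prior_p$L1))
  st$d$L1 <- c(5, 5, 0, 0)
  st$edge_count_est[["L1"]] <- 5
  st <- e_step(st, obs)
  expect_equal(st$p$L1[1, 2], 1) # 25/9 capped at 1
  st$edge_count_est[["L1"]] <- 0
  expect_error(e_step(st, obs), class = "muxrec_degenerate_layer")
})

test_that("expectation step clamps observed entries to the observation", {
  net <- study_net(seed = 2)
  obs <- mask_nodes(net, 0.5, seed = 3)
  st <- blank_state(obs)
  st <- e_step(st, obs)
  for (l in net$layer_ids) {
    sel <- obs$mask[[l]]
    expect_identical(st$p[[l]][sel], obs$X[[l]][sel])
    # prior keeps the un-clamped model value for all pairs
    expect_true(all(st$prior_p[[l]] >= 0 & st$prior_p[[l]] <= 1))
  }
})

test_that("aggregation step applies the interlayer Bayes update", {
  # two layers over 3 nodes, nothing observed, A forced to 1 on pair (1,2)
  net <- multiplex_network(tibble::tibble(layer = c("L1", "L2"),
                                          from = "a", to = "b"),
                           nodes = "c")
  obs <- mask_nodes(net, 0, seed = 1)
  st <- blank_state(obs)
  st$prior_p <- lapply(st$p, function(m) m * 0)
  st$prior_p$L1[1, 2] <- st$prior_p$L1[2, 1] <- 0.5
  st$prior_p$L2[1, 2] <- st$prior_p$L2[2, 1] <- 0.5
  st$A[1, 2] <- st$A[2, 1] <- 1
  st2 <- a_step(st, obs, mode = "evidence")
  expect_equal(st2$p$L1[1, 2], 0.5 / (1 - 0.25)) # = 2/3
  expect_equal(st2$p$L2[1, 2], 2 / 3)
  # a certain link in the other layer makes the denominator 1: update = prior
  st$prior_p$L2[1, 2] <- st$prior_p$L2[2, 1] <- 1
  st3 <- a_step(st, obs, mode = "evidence")
  expect_equal(st3$p$L1[1, 2], 0.5)
  # all-zero priors: 0/0 guarded, entry untouched
  st$prior_p$L1[1, 2] <- st$prior_p$L1[2, 1] <- 0
  st$prior_p$L2[1, 2] <- st$prior_p$L2[2, 1] <- 0
  before <- st$p$L1[1, 2]
  st4 <- a_step(st, obs, mode = "evidence")
  expect_equal(st4$p$L1[1, 2], before)
})

test_that("aggregation never decreases probabilities and respects clamping", {
  net <- study_net(seed = 4)
  obs <- mask_nodes(net, 0.5, seed = 5)
  st <- e_step(blank_state(obs), obs)
  for (mode in c("evidence", "all_pairs")) {
    st2 <- a_step(st, obs, mode = mode)
    for (l in net$layer_ids) {
      unobs <- !obs$mask[[l]]
      diag(unobs) <- FALSE
      expect_true(all(st2$p[[l]][unobs] >= st$prior_p[[l]][unobs] - 1e-12))
      expect_true(all(st2$p[[l]] <= 1))
      sel <- obs$mask[[l]]
      expect_identical(st2$p[[l]][sel], obs$X[[l]][sel])
    }
  }
})

test_that("maximization steps keep degrees and edge counts self-consistent", {
  net <- study_net(seed = 6)
  obs <- mask_nodes(net, 0.5, seed = 7)
  # self-consistent variant: d = row sums, 2|E| = sum(d) exactly
  st <- e_step(init_state(obs, ema_config(edge_count = "estimate", seed = 1)), obs)
  st <- m_step_approx(st)
  for (l in net$layer_ids) {
    expect_equal(st$d[[l]], rowSums(st$p[[l]]))
    expect_equal(sum(st$d[[l]]), 2 * st$edge_count_est[[l]])
  }
  # anchored variant: degree mass pinned to the fixed edge count
  sta <- e_step(init_state(obs, ema_config(seed = 1)), obs)
  fx <- sta$fixed_edge_count
  sta <- m_step_approx(sta)
  for (l in net$layer_ids) {
    expect_equal(sum(sta$d[[l]]), 2 * fx[[l]], tolerance = 1e-12)
    expect_equal(sta$edge_count_est[[l]], fx[[l]])
  }
})

test_that("fully observed input makes the approximate M-step exact", {
  net <- toy_net()
  obs <- mask_nodes(net, 1, seed = 1)
  st <- e_step(init_state(obs, ema_config(edge_count = "estimate", seed = 2)), obs)
  st <- m_step_approx(st)
  for (l in net$layer_ids) {
    expect_equal(st$d[[l]], rowSums(adjacency(net, l)), ignore_attr = TRUE)
  }
})

# ---- the exact degree solution ---------------------------------------------

test_that("the exact degree root satisfies its fixed-point relation", {
  expect_equal(solve_degree(3, 10), 10 - sqrt(43))
  expect_equal(solve_degree(0, 10), 0)
  # closed form at |E| = 1000, s = 3, and the large-|E| limit (~0.1% off s)
  expect_equal(solve_degree(3, 1000), 1000 - sqrt(1000^2 - 6000 + 3))
  expect_equal(solve_degree(3, 1000), 3, tolerance = 1.5e-3)
  # residual oracle on a random feasible grid: d(2|E| - d) = (2|E| - 1) s
  withr::with_seed(42, {
    E <- runif(500, 5, 5000)
    s <- runif(500) * (E^2 / (2 * E - 1)) * 0.99
    d <- solve_degree(s, E)
    resid <- abs(d * (2 * E - d) - (2 * E - 1) * s) / pmax(1, (2 * E - 1) * s)
    expect_lt(max(resid), 1e-8)
    expect_true(all(d >= 0 & d <= E)) # smaller root only
  })
})

test_that("infeasible rows trigger the giant-hub error and name the node", {
  expect_error(solve_degree(6, 10), class = "muxrec_infeasible")
  net <- toy_net()
  obs <- mask_nodes(net, 0, seed = 1)
  st <- e_step(blank_state(obs), obs)
  st$p$L1[] <- 1
  diag(st$p$L1) <- 0
  st$fixed_edge_count[] <- NA_real_
  st$edge_count_est[["L1"]] <- 3 # row sums are 4 > feasible bound
  expect_error(m_step_exact(st), class = "muxrec_infeasible", regexp = "L1")
})

test_that("exact and approximate M-steps agree when edges dominate degrees", {
  net <- study_net(seed = 8)
  obs <- mask_nodes(net, 0.5, seed = 9)
  st <- e_step(init_state(obs, ema_config(edge_count = "estimate", seed = 3)), obs)
  ex <- m_step_exact(st)
  ap <- m_step_approx(st)
  for (l in net$layer_ids) {
    s <- rowSums(st$p[[l]])
    big <- st$edge_count_est[[l]] >= 100 * s
    if (any(big)) {
      expect_equal(ex$d[[l]][big], ap$d[[l]][big], tolerance = 0.01)
    }
  }
})

# ---- convergence error ------------------------------------------------------

test_that("the convergence error is the mean absolute change over unobserved pairs", {
  net <- toy_net()
  obs <- mask_nodes(net, 0, seed = 1)
  p0 <- lapply(net$adj, function(m) m * 0)
  p1 <- p0
  expect_equal(convergence_error(p0, p0, obs), 0)
  # two changed entries among 2 * C(5,2) = 20 unobserved pairs
  p1$L1[1, 2] <- p1$L1[2, 1] <- 0.1
  p1$L2[1, 3] <- p1$L2[3, 1] <- 0.3
  expect_equal(convergence_error(p0, p1, obs), (0.1 + 0.3) / 20)
  full <- mask_nodes(net, 1, seed = 1)
  expect_equal(convergence_error(p0, p1, full), 0)
})

# ---- the full solver --------------------------------------------------------

test_that("fully observed networks are recovered exactly for any seed", {
  net <- study_net(seed = 10)
  obs <- mask_nodes(net, 1, seed = 11)
  for (seed in c(1, 99, 12345)) {
    fit <- run_ema(obs, ema_config(seed = seed))
    expect_true(fit$converged)
    expect_lte(fit$iterations, 2)
    expect_equal(fit$trace[fit$iterations], 0)
    for (l in net$layer_ids) {
      expect_equal(fit$p[[l]], adjacency(net, l), ignore_attr = TRUE)
    }
  }
})

test_that("solver state stays in range with observed entries clamped throughout", {
  net <- study_net(seed = 12)
  obs <- mask_nodes(net, 0.4, seed = 13)
  for (ec in c("anchor", "estimate")) {
    fit <- run_ema(obs, ema_config(edge_count = ec, max_iterations = 15, seed = 2))
    for (l in net$layer_ids) {
      expect_true(all(fit$p[[l]] >= 0 & fit$p[[l]] <= 1))
      expect_true(all(fit$d[[l]] >= 0))
      expect_equal(fit$p[[l]], t(fit$p[[l]]))
      sel <- obs$mask[[l]]
      expect_identical(fit$p[[l]][sel], obs$X[[l]][sel])
    }
    expect_length(fit$trace, fit$iterations)
  }
})

test_that("with one layer the aggregation step is a no-op", {
  net <- generate_multiplex(60, 1, degree = "poisson:3", seed = 14)
  obs <- mask_nodes(net, 0.5, seed = 15)
  fa <- run_ema(obs, ema_config(a_step = "evidence", seed = 6))
  fo <- run_ema(obs, ema_config(a_step = "off", seed = 6))
  expect_identical(fa$p, fo$p)
  expect_identical(fa$trace, fo$trace)
})

test_that("identical seeds reproduce identical fits", {
  net <- study_net(seed = 16)
  obs <- mask_nodes(net, 0.5, seed = 17)
  f1 <- run_ema(obs, ema_config(seed = 8, max_iterations = 20))
  f2 <- run_ema(obs, ema_config(seed = 8, max_iterations = 20))
  expect_identical(f1$p, f2$p)
  expect_identical(f1$trace, f2$trace)
})

test_that("aggregate evidence follows the observed OR rule", {
  net <- toy_net()
  obs <- mask_nodes(net, observed_nodes = list(L1 = c("a", "b", "c"),
                                               L2 = c("a", "b", "d")))
  st <- blank_state(obs)
  ix <- function(u, v) c(match(u, net$node_ids), match(v, net$node_ids))
  ab <- ix("a", "b")
  expect_equal(st$A[ab[1], ab[2]], 1)   # observed link in both layers
  bc <- ix("b", "c")
  expect_equal(st$A[bc[1], bc[2]], 1)   # observed link in L1 only
  # a-c observed absent in L1 but unobserved in L2: unknown
  ac <- ix("a", "c")
  expect_true(is.na(st$A[ac[1], ac[2]]))
})

test_that("tidy and glance expose the fit in tabular form", {
  net <- generate_multiplex(30, 2, degree = "poisson:2", overlap = 0.5, seed = 18)
  obs <- mask_nodes(net, 0.6, seed = 19)
  fit <- run_ema(obs, ema_config(seed = 20))
  td <- tidy(fit)
  expect_true(all(!td$observed))
  expect_equal(nrow(td), sum(vapply(net$layer_ids, function(l)
    sum(unobserved_pair_mask(obs, l)), numeric(1))))
  expect_true(all(td$probability >= 0 & td$probability <= 1))
  full <- tidy(fit, include_observed = TRUE)
  expect_equal(nrow(full), 2 * choose(30, 2))
  gl <- glance(fit)
  expect_equal(gl$method, "ema")
  expect_equal(gl$iterations, fit$iterations)
})
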