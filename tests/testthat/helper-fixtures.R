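# fixtures built in code, shared across test files

triangle_net <- function() {
  multiplex_network(tibble::tibble(
    layer = "L1", from = c("a", "b", "c"), to = c("b", "c", "a")))
}

# two layers over {a..e}: a square in L1, a path in L2, sharing edge a-b
toy_net <- function() {
  multiplex_network(tibble::tibble(
    layer = c("L1", "L1", "L1", "L1", "L2", "L2", "L2"),
    from = c("a", "b", "c", "a", "a", "c", "d"),
    to = c("b", "c", "d", "d", "b", "d", "e")))
}

# the synthetic regime used for the method-comparison studies
study_net <- function(m = 2, seed = 1) {
  generate_multiplex(200, m, degree = "poisson:3", overlap = 0.7, seed = seed)
}

# a hand-rollable state for unit-testing single solver steps
blank_state <- function(obs, cfg = ema_config(seed = 1)) init_state(obs, cfg)
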