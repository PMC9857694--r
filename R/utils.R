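# internal helpers shared across modules

# deterministic fan-out of a master seed into per-component seeds;
# kept below 2^31-1 so it is always a valid R integer seed
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483647
  as.integer(h)
}

# evaluate `code` under a fixed seed without disturbing the caller's RNG;
# seed = NULL means "use the RNG stream as-is"
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# logical mask of i<j (upper-triangle) positions of an n x n matrix
upper_mask <- function(n) upper.tri(matrix(FALSE, n, n))

# canonical rank of upper-triangle positions: row-major (i, then j)
canonical_pair_rank <- function(idx, n) {
  j <- ((idx - 1L) %/% n) + 1L
  i <- ((idx - 1L) %% n) + 1L
  (i - 1) * n + j
}

symmetrize_upper <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

`%||%` <- rlang::`%||%`
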