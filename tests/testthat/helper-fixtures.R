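# Shared fixture builders. Everything is generated in code; sizes are
# kept tiny so individual tests stay fast.

## a deterministic small paired dataset (no planted signal structure)
tiny_data <- function(N = 4L, V = 3L, P = 2L, seed = 99L) {
  set.seed(seed)
  pairs <- edge_pairs(V)
  E <- matrix(rnorm(N * nrow(pairs)), N)
  Y <- matrix(rnorm(N * P), N)
  list(conn = connectivity_data(E, n_regions = V),
       behav = behavior_data(Y))
}

## a model state with simple deterministic values
tiny_state <- function(N = 4L, V = 3L, P = 2L, seed = 7L) {
  set.seed(seed)
  model_state(
    beta = 0, a = rep(0, N), sigma2 = 1,
    gamma = 0, b = rep(0, P), tau2 = 1,
    Z = matrix(rnorm(N * V), N, V), theta = rnorm(N),
    Sigma = diag(V + 1L)
  )
}

## symmetric matrix from an upper-triangle spec, NA diagonal not needed
sym_from_upper <- function(V, vals) {
  m <- matrix(0, V, V)
  m[upper.tri(m)] <- vals
  m + t(m)
}

## Monte Carlo standard error helper
mc_se <- function(x) stats::sd(x) / sqrt(length(x))
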