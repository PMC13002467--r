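# Simulation-study generator. Latent vectors (z_i, theta_i) are drawn
# MVN(0, Sigma) with unit variances; a randomly placed subset of regions
# carries cross-covariance 0.9 with the behavior trait (and the matching
# within-connectivity covariances, which keeps Sigma positive definite);
# edges add N(0, 1/SNR) noise and the single behavior item adds N(0, 0.5)
# noise. Intercepts and covariate effects are zero.

#' Simulation configuration
#'
#' The default grid values are the study conditions: sample sizes
#' {500, 1000, 2000}, network sizes {20, 70}, signal-to-noise ratios
#' {0.5, 1} and signal proportions {0.1, 0.3}, with cross-covariance 0.9
#' and behavior noise variance 0.5. Any positive values are accepted for
#' exploratory use.
#'
#' @param n_participants Sample size N.
#' @param n_regions Number of regions V.
#' @param snr Signal-to-noise ratio; edge noise variance is 1/snr with the
#'   latent variances held at 1.
#' @param signal_proportion Fraction of regions with nonzero
#'   connectivity-behavior cross-covariance, in [0, 1].
#' @param cross_cov_value Planted cross-covariance value.
#' @param behavior_noise_var Behavior item noise variance.
#' @param n_behavior_items Number of behavior items (the study design uses 1).
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 500L, n_regions = 20L,
                              snr = 1, signal_proportion = 0.1,
                              cross_cov_value = 0.9,
                              behavior_noise_var = 0.5,
                              n_behavior_items = 1L, seed = 1L) {
  if (n_participants < 1L || n_regions < 2L) stop("need N >= 1 and V >= 2")
  if (snr <= 0) stop("snr must be positive")
  if (signal_proportion < 0 || signal_proportion > 1) {
    stop("signal_proportion must lie in [0, 1]")
  }
  if (behavior_noise_var <= 0) stop("behavior_noise_var must be positive")
  structure(list(
    n_participants = as.integer(n_participants),
    n_regions = as.integer(n_regions), snr = snr,
    signal_proportion = signal_proportion,
    cross_cov_value = cross_cov_value,
    behavior_noise_var = behavior_noise_var,
    n_behavior_items = as.integer(n_behavior_items),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Construct the true joint latent covariance of a simulation scenario
#'
#' Starts from the identity, selects round(signal_proportion * V) regions
#' uniformly at random, and sets both their cross-covariances with the
#' behavior trait and the covariances among the selected regions to
#' `cross_cov_value`. The result is checked for positive definiteness;
#' the equicorrelated signal block guarantees it for values below 1.
#'
#' @param config A `simulation_config`.
#' @return List with `true_Sigma` ((V+1) x (V+1)) and `signal_regions`
#'   (integer vector, possibly empty).
#' @export
build_true_sigma <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  V <- config$n_regions
  k <- round(config$signal_proportion * V)
  set.seed(config$seed)
  signal <- if (k > 0) sort(sample.int(V, k)) else integer(0)
  Sigma <- diag(V + 1L)
  if (k > 0) {
    rho <- config$cross_cov_value
    Sigma[signal, V + 1L] <- rho
    Sigma[V + 1L, signal] <- rho
    block <- matrix(rho, k, k); diag(block) <- 1
    Sigma[signal, signal] <- block
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("true Sigma is not positive definite at cross_cov_value = ",
         config$cross_cov_value, "; choose a smaller value")
  }
  list(true_Sigma = Sigma, signal_regions = signal)
}

#' Simulate a dataset from the generative model
#'
#' Draws (z_i, theta_i) i.i.d. MVN(0, true Sigma), forms edges
#' x_{u,v,i} = z_{u,i} z_{v,i} + N(0, 1/snr) for u < v, and behavior
#' items y_{i,p} = theta_i + N(0, behavior_noise_var). Individual
#' intercepts and covariate effects are zero; covariates are
#' intercept-only. Deterministic given `config$seed`.
#'
#' @param config A `simulation_config`.
#' @return List with `connectivity` (`connectivity_data`), `behavior`
#'   (`behavior_data`) and `truth` (class `simulation_truth`: `true_Sigma`,
#'   `signal_regions`, `true_sigma2`, `true_tau2`, `Z`, `theta`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ts <- build_true_sigma(config)  # also seeds the RNG
  N <- config$n_participants; V <- config$n_regions
  P <- config$n_behavior_items
  F_ <- matrix(stats::rnorm(N * (V + 1L)), N) %*% chol(ts$true_Sigma)
  Z <- F_[, seq_len(V), drop = FALSE]
  theta <- F_[, V + 1L]
  pairs <- edge_pairs(V)
  sigma2 <- 1 / config$snr
  E <- .bilinear(Z, pairs) +
    matrix(stats::rnorm(N * nrow(pairs), sd = sqrt(sigma2)), N)
  Y <- theta + matrix(stats::rnorm(N * P, sd = sqrt(config$behavior_noise_var)), N, P)
  truth <- structure(list(
    true_Sigma = ts$true_Sigma, signal_regions = ts$signal_regions,
    true_sigma2 = sigma2, true_tau2 = config$behavior_noise_var,
    Z = Z, theta = theta
  ), class = "simulation_truth")
  list(
    connectivity = connectivity_data(E, n_regions = V),
    behavior = behavior_data(Y),
    truth = truth
  )
}

#' The full factorial scenario grid of the simulation study
#'
#' All 24 combinations of N in {500, 1000, 2000}, V in {20, 70}, SNR in
#' {0.5, 1} and signal proportion in {0.1, 0.3}, in a stable row-major
#' ordering (signal proportion varying fastest). Scenario seeds are
#' derived deterministically from `base_seed`.
#'
#' @param base_seed Integer; scenario i gets seed `base_seed * 1000 + i`.
#' @return List of 24 `simulation_config` objects.
#' @export
scenario_grid <- function(base_seed = 1L) {
  grid <- expand.grid(
    signal_proportion = c(0.1, 0.3),
    snr = c(0.5, 1),
    n_regions = c(20L, 70L),
    n_participants = c(500L, 1000L, 2000L),
    KEEP.OUT.ATTRS = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    simulation_config(
      n_participants = grid$n_participants[i],
      n_regions = grid$n_regions[i],
      snr = grid$snr[i],
      signal_proportion = grid$signal_proportion[i],
      seed = as.integer(base_seed) * 1000L + i
    )
  })
}
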