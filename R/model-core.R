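# Generative model: for participant i and regions u < v,
#   x_{u,v,i} = w_i' beta + a_i + z_{u,i} z_{v,i} + e,   e ~ N(0, sigma2)
#   y_{i,p}   = h_i' gamma + b_p + theta_i + eps,        eps ~ N(0, tau2)
#   (z_i, theta_i) ~ MVN(0, Sigma),  Sigma (V+1) x (V+1) with blocks
#   Lambda_z (V x V), Lambda_ztheta (V x 1), Lambda_theta (scalar).
# Nonzero entries of Lambda_ztheta are the region-level biomarkers.

#' Construct a model state
#'
#' Holds all current parameter values of one Gibbs iteration.
#'
#' @param beta Length-Q connectivity covariate effects.
#' @param a Length-N participant connectivity intercepts.
#' @param sigma2 Edge noise variance (> 0).
#' @param gamma Length-Q' behavior covariate effects.
#' @param b Length-P item intercepts.
#' @param tau2 Item noise variance (> 0).
#' @param Z N x V matrix of latent region positions.
#' @param theta Length-N latent behavior traits.
#' @param Sigma (V+1) x (V+1) symmetric positive-definite joint latent
#'   covariance.
#' @return An object of class `model_state`.
#' @export
model_state <- function(beta, a, sigma2, gamma, b, tau2, Z, theta, Sigma) {
  Z <- as.matrix(Z)
  Sigma <- as.matrix(Sigma)
  V <- ncol(Z)
  if (!all(dim(Sigma) == V + 1L)) {
    stop("Sigma must be ", V + 1L, " x ", V + 1L, " for V = ", V, " regions")
  }
  if (sigma2 <= 0 || tau2 <= 0) stop("sigma2 and tau2 must be strictly positive")
  if (length(a) != nrow(Z) || length(theta) != nrow(Z)) {
    stop("a and theta must have length N = nrow(Z) = ", nrow(Z))
  }
  structure(list(
    beta = as.numeric(beta), a = as.numeric(a), sigma2 = sigma2,
    gamma = as.numeric(gamma), b = as.numeric(b), tau2 = tau2,
    Z = Z, theta = as.numeric(theta), Sigma = Sigma
  ), class = "model_state")
}

## internal: bilinear products z_u z_v for all pairs, N x M
.bilinear <- function(Z, pairs) {
  Z[, pairs[, "u"], drop = FALSE] * Z[, pairs[, "v"], drop = FALSE]
}

## internal: N x M matrix of model means w_i'beta + a_i + z_u z_v
.edge_mean_matrix <- function(state, conn) {
  drift <- as.numeric(conn$covariates %*% state$beta) + state$a
  .bilinear(state$Z, conn$pairs) + drift
}

## internal: N x P matrix of model means h_i'gamma + b_p + theta_i
.item_mean_matrix <- function(state, behav) {
  drift <- as.numeric(behav$covariates %*% state$gamma) + state$theta
  outer(drift, rep(1, length(state$b))) + rep(state$b, each = behav$n_participants)
}

.check_state_conn <- function(state, conn) {
  if (ncol(state$Z) != conn$n_regions) {
    stop("state has V = ", ncol(state$Z), " regions but data has V = ", conn$n_regions)
  }
  if (nrow(state$Z) != conn$n_participants) {
    stop("state has N = ", nrow(state$Z), " participants but data has N = ",
         conn$n_participants)
  }
  if (length(state$beta) != ncol(conn$covariates)) {
    stop("state has Q = ", length(state$beta), " covariate effects but data has Q = ",
         ncol(conn$covariates))
  }
  invisible(TRUE)
}

.check_state_behav <- function(state, behav) {
  if (length(state$b) != behav$n_items) {
    stop("state has P = ", length(state$b), " item intercepts but data has P = ",
         behav$n_items)
  }
  if (nrow(state$Z) != behav$n_participants) {
    stop("state has N = ", nrow(state$Z), " participants but behavior has N = ",
         behav$n_participants)
  }
  if (length(state$gamma) != ncol(behav$covariates)) {
    stop("state has Q' = ", length(state$gamma), " covariate effects but data has Q' = ",
         ncol(behav$covariates))
  }
  invisible(TRUE)
}

#' Model mean of one participant's connectivity matrix
#'
#' Entry (u, v), u != v, is w_i' beta + a_i + z_{u,i} z_{v,i}; the
#' diagonal is not modeled and returned as `NA`. The bilinear term makes
#' the mean invariant to negating the participant's whole latent vector.
#'
#' @param state A `model_state`.
#' @param data A `connectivity_data`.
#' @param participant Participant index.
#' @return Symmetric V x V matrix with `NA` diagonal.
#' @export
connectivity_mean <- function(state, data, participant) {
  .check_state_conn(state, data)
  i <- as.integer(participant)
  if (i < 1L || i > data$n_participants) stop("participant index out of range")
  V <- data$n_regions
  z <- state$Z[i, ]
  m <- tcrossprod(z) + sum(data$covariates[i, ] * state$beta) + state$a[i]
  diag(m) <- NA_real_
  dimnames(m) <- list(data$region_labels, data$region_labels)
  m
}

#' Model mean of one participant's behavior items
#'
#' Entry p is h_i' gamma + b_p + theta_i. The decomposition into item
#' intercepts and a person trait is only softly identified (adding a
#' constant to theta_i and subtracting it from every b_p leaves the mean
#' unchanged); the zero-centered priors resolve the location.
#'
#' @param state A `model_state`.
#' @param data A `behavior_data`.
#' @param participant Participant index.
#' @return Length-P numeric vector.
#' @export
behavior_mean <- function(state, data, participant) {
  .check_state_behav(state, data)
  i <- as.integer(participant)
  if (i < 1L || i > data$n_participants) stop("participant index out of range")
  drop(sum(data$covariates[i, ] * state$gamma) + state$b + state$theta[i])
}

#' Joint log density of data and latent variables
#'
#' Sum of the Gaussian edge log likelihood over observed pairs u < v, the
#' Gaussian item log likelihood over observed items, and the MVN(0, Sigma)
#' log prior of each participant's joint latent vector (z_i, theta_i).
#' Fixed-effect priors are excluded; this is the quantity the latent-
#' variable Gibbs updates leave invariant.
#'
#' @param state A `model_state`.
#' @param conn A `connectivity_data`.
#' @param behav A `behavior_data`.
#' @return Finite scalar log density.
#' @export
joint_log_density <- function(state, conn, behav) {
  .check_state_conn(state, conn)
  .check_state_behav(state, behav)
  R <- conn$edges - .edge_mean_matrix(state, conn)
  ll_edge <- sum(stats::dnorm(R[conn$mask], 0, sqrt(state$sigma2), log = TRUE))
  Ty <- behav$outcomes - .item_mean_matrix(state, behav)
  ll_item <- sum(stats::dnorm(Ty[behav$mask], 0, sqrt(state$tau2), log = TRUE))

  K <- ncol(state$Sigma)
  ch <- tryCatch(chol(state$Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("Sigma is not positive definite")
  F_ <- cbind(state$Z, state$theta)
  ## MVN(0, Sigma) log density for each row of F_
  half <- forwardsolve(t(ch), t(F_))
  quad <- colSums(half^2)
  ld <- 2 * sum(log(diag(ch)))
  ll_prior <- sum(-0.5 * (K * log(2 * pi) + ld + quad))
  ll_edge + ll_item + ll_prior
}

#' Partition the joint latent precision matrix
#'
#' Inverts Sigma and returns the blocks of the precision Q = Sigma^-1:
#' `Qz` (V x V, regions), `Qt` (scalar, behavior trait) and the cross
#' block `Qtz` (1 x V). These blocks drive the prior terms of the
#' latent-variable full conditionals.
#'
#' @param Sigma (V+1) x (V+1) symmetric positive-definite matrix.
#' @return An object of class `precision_partition` with elements `Qz`,
#'   `Qtz`, `Qt`, and the full precision `Q`.
#' @export
partition_precision <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  K <- nrow(Sigma)
  if (K != ncol(Sigma) || max(abs(Sigma - t(Sigma))) > 1e-8) {
    stop("Sigma must be symmetric")
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("Sigma is not positive definite (condition number ",
         format(max(ev) / max(min(ev), .Machine$double.eps), digits = 3),
         ", smallest eigenvalue ", format(min(ev), digits = 3), ")")
  }
  Q <- chol2inv(chol(Sigma))
  V <- K - 1L
  structure(list(
    Qz = Q[seq_len(V), seq_len(V), drop = FALSE],
    Qtz = Q[K, seq_len(V), drop = FALSE],
    Qt = Q[K, K],
    Q = Q
  ), class = "precision_partition")
}
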