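# Gibbs sampler. All full conditionals are conjugate:
#   (beta, a)   normal, given edge residuals
#   sigma^-2    gamma(1/2 + nObs/2, 1/2 + SSE/2)
#   (gamma, b)  normal, given item residuals
#   tau^-2      gamma(1/2 + nObs/2, 1/2 + SSE/2)
#   {Z, theta}  per-participant normal scans (regions in index order, then
#               the trait), participants vectorized
#   Sigma       inverse-Wishart(S0 + F'^T F', N + m0), F' = [Z, theta]
# After burn-in the per-participant latent signs are aligned to the first
# post-burn-in draw (reflection indeterminacy of the bilinear term).

#' Sampler configuration
#'
#' @param n_iterations Total Gibbs iterations.
#' @param burn_in Discarded initial iterations (< n_iterations).
#' @param thinning Keep every `thinning`-th post-burn-in draw.
#' @param n_starts Number of random initializations for [multi_start_fit()].
#' @param seed Integer RNG seed.
#' @param store_latents If TRUE, keep per-draw Z and theta (memory heavy;
#'   intended for small problems).
#' @param region_marginal_prior If TRUE, the z full conditional uses only
#'   the 2 x 2 region/trait submatrix of Sigma for its prior term instead
#'   of the exact conditional from the full joint precision (see the
#'   methods vignette).
#' @param verbose If TRUE, log a line every 100 iterations.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_iterations = 3000L, burn_in = 1000L,
                           thinning = 1L, n_starts = 10L, seed = 1L,
                           store_latents = FALSE,
                           region_marginal_prior = FALSE,
                           verbose = FALSE) {
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in)
  thinning <- as.integer(thinning)
  if (burn_in < 0L || burn_in >= n_iterations) {
    stop("burn_in must be non-negative and smaller than n_iterations")
  }
  if (thinning < 1L) stop("thinning must be a positive integer")
  if ((n_iterations - burn_in) %/% thinning < 10L) {
    stop("configuration retains fewer than 10 draws; increase n_iterations ",
         "or reduce thinning")
  }
  structure(list(
    n_iterations = n_iterations, burn_in = burn_in, thinning = thinning,
    n_starts = as.integer(n_starts), seed = as.integer(seed),
    store_latents = isTRUE(store_latents),
    region_marginal_prior = isTRUE(region_marginal_prior),
    verbose = isTRUE(verbose)
  ), class = "sampler_config")
}

#' Draw an initial model state from the priors
#'
#' beta, gamma, a, b are drawn from their priors, sigma2 and tau2 start at
#' 1, Z and theta are i.i.d. standard normal and Sigma is the identity.
#' Deterministic given `seed`.
#'
#' @param conn A `connectivity_data`.
#' @param behav A paired `behavior_data` (same N).
#' @param priors A `prior_spec` for V = `conn$n_regions`.
#' @param seed Integer RNG seed.
#' @return A `model_state`.
#' @export
initialize_state <- function(conn, behav, priors, seed = 1L) {
  if (conn$n_participants != behav$n_participants) {
    stop("connectivity has N = ", conn$n_participants,
         " but behavior has N = ", behav$n_participants)
  }
  if (priors$n_regions != conn$n_regions) {
    stop("priors are for V = ", priors$n_regions, " but data has V = ",
         conn$n_regions)
  }
  set.seed(as.integer(seed))
  N <- conn$n_participants; V <- conn$n_regions
  Q <- ncol(conn$covariates); Qp <- ncol(behav$covariates)
  P <- behav$n_items
  model_state(
    beta = stats::rnorm(Q),
    a = stats::rnorm(N, sd = priors$intercept_sd),
    sigma2 = 1,
    gamma = stats::rnorm(Qp),
    b = stats::rnorm(P, sd = priors$intercept_sd),
    tau2 = 1,
    Z = matrix(stats::rnorm(N * V), N, V),
    theta = stats::rnorm(N),
    Sigma = diag(V + 1L)
  )
}

## internal: mask matrix for the compiled kernels (dummy when complete)
.mask_arg <- function(conn, all_obs) {
  if (all_obs) matrix(1, 1L, 1L) else (conn$mask + 0)
}

## internal: draw MVN(mean, Prec^-1) given precision matrix
.rmvnorm_prec <- function(lin, Prec) {
  ch <- chol(Prec)
  mu <- backsolve(ch, backsolve(ch, lin, transpose = TRUE))
  drop(mu + backsolve(ch, stats::rnorm(length(lin))))
}

#' Gibbs update of the connectivity regression (beta, a)
#'
#' Draws beta from its conjugate multivariate-normal full conditional
#' (prior MVN(0, I_Q)) and each participant intercept a_i from its
#' conjugate normal full conditional (prior N(0, intercept_sd^2)), given
#' the bilinear edge residuals. Only observed edges contribute.
#'
#' @param state A `model_state`.
#' @param conn A `connectivity_data`.
#' @param priors A `prior_spec`.
#' @param zz Optional precomputed bilinear product matrix (internal
#'   speed-up for [run_chain()]).
#' @return The updated `model_state`.
#' @export
update_connectivity_regression <- function(state, conn, priors = prior_spec(conn$n_regions),
                                           zz = NULL) {
  .check_state_conn(state, conn)
  W <- conn$covariates
  if (is.null(zz)) zz <- .bilinear(state$Z, conn$pairs)
  all_obs <- all(conn$mask)
  N <- nrow(conn$edges)
  st_ <- .edge_resid_stats_cpp(conn$edges, zz, numeric(N), .mask_arg(conn, all_obs),
                               all_obs)
  rs_base <- st_$row_sums
  if (any(!is.finite(rs_base))) stop("non-finite edge residuals in beta update")
  m_i <- if (all_obs) rep.int(ncol(conn$edges), N) else rowSums(conn$mask)
  ## beta | rest: residual sums subtract a_i once per observed edge
  s_i <- rs_base - m_i * state$a
  Prec <- diag(ncol(W)) + crossprod(W, W * m_i) / state$sigma2
  lin <- crossprod(W, s_i) / state$sigma2
  state$beta <- .rmvnorm_prec(lin, Prec)
  ## a | rest, given the fresh beta
  prec_a <- 1 / priors$intercept_sd^2 + m_i / state$sigma2
  mu_a <- ((rs_base - m_i * as.numeric(W %*% state$beta)) / state$sigma2) / prec_a
  state$a <- stats::rnorm(length(mu_a), mu_a, sqrt(1 / prec_a))
  state
}

#' Gibbs update of the edge noise variance
#'
#' Draws sigma^-2 from gamma(shape + nObs/2, rate + SSE/2) where nObs is
#' the number of observed edges and SSE the squared edge residuals.
#'
#' @inheritParams update_connectivity_regression
#' @return The updated `model_state`.
#' @export
update_sigma2 <- function(state, conn, priors = prior_spec(conn$n_regions),
                          zz = NULL) {
  .check_state_conn(state, conn)
  if (is.null(zz)) zz <- .bilinear(state$Z, conn$pairs)
  drift <- as.numeric(conn$covariates %*% state$beta) + state$a
  all_obs <- all(conn$mask)
  sse <- .edge_resid_stats_cpp(conn$edges, zz, drift, .mask_arg(conn, all_obs),
                               all_obs)$sse
  if (!is.finite(sse)) stop("non-finite edge residual sum of squares")
  n_obs <- sum(conn$mask)
  if (n_obs == 0L) stop("no observed edges; cannot update sigma2")
  state$sigma2 <- 1 / stats::rgamma(1L, priors$sigma_inv_shape + n_obs / 2,
                                    priors$sigma_inv_rate + sse / 2)
  state
}

#' Gibbs update of the behavior regression (gamma, b)
#'
#' Draws gamma from its conjugate multivariate-normal full conditional
#' and each item intercept b_p from its conjugate normal full conditional
#' (priors standard normal), given the item residuals. Only observed
#' items contribute.
#'
#' @param state A `model_state`.
#' @param behav A `behavior_data`.
#' @param priors A `prior_spec`.
#' @return The updated `model_state`.
#' @export
update_behavior_regression <- function(state, behav,
                                       priors = prior_spec(ncol(state$Z))) {
  .check_state_behav(state, behav)
  H <- behav$covariates
  P <- behav$n_items
  ## gamma | rest: residuals y - b_p - theta over observed items
  R <- (behav$outcomes - rep(state$b, each = nrow(H)) - state$theta) * behav$mask
  if (any(!is.finite(R))) stop("non-finite item residuals in gamma update")
  p_i <- rowSums(behav$mask)
  Prec <- diag(ncol(H)) + crossprod(H, H * p_i) / state$tau2
  lin <- crossprod(H, rowSums(R)) / state$tau2
  state$gamma <- .rmvnorm_prec(lin, Prec)
  ## b_p | rest
  drift <- as.numeric(H %*% state$gamma) + state$theta
  R0 <- (behav$outcomes - drift) * behav$mask
  n_p <- colSums(behav$mask)
  prec_b <- 1 / priors$intercept_sd^2 + n_p / state$tau2
  mu_b <- (colSums(R0) / state$tau2) / prec_b
  state$b <- stats::rnorm(P, mu_b, sqrt(1 / prec_b))
  state
}

#' Gibbs update of the item noise variance
#'
#' Draws tau^-2 from gamma(shape + nObs/2, rate + SSE/2) over observed
#' behavior items.
#'
#' @inheritParams update_behavior_regression
#' @return The updated `model_state`.
#' @export
update_tau2 <- function(state, behav, priors = prior_spec(ncol(state$Z))) {
  .check_state_behav(state, behav)
  R <- (behav$outcomes - .item_mean_matrix(state, behav)) * behav$mask
  sse <- sum(R^2)
  if (!is.finite(sse)) stop("non-finite item residual sum of squares")
  n_obs <- sum(behav$mask)
  if (n_obs == 0L) stop("no observed behavior items; cannot update tau2")
  state$tau2 <- 1 / stats::rgamma(1L, priors$tau_inv_shape + n_obs / 2,
                                  priors$tau_inv_rate + sse / 2)
  state
}

## internal: per-region neighbor indexing, computed once per data set
.region_index <- function(pairs, V) {
  lapply(seq_len(V), function(u) {
    sel <- which(pairs[, "u"] == u | pairs[, "v"] == u)
    nbr <- ifelse(pairs[sel, "u"] == u, pairs[sel, "v"], pairs[sel, "u"])
    list(cols = sel, nbr = nbr)
  })
}

#' Gibbs update of the latent variables {Z, theta}
#'
#' For each participant, region positions z_{u,i} are redrawn in index
#' order from their normal full conditionals (bilinear edge information
#' plus the MVN(0, Sigma) prior conditioned on the other latents), then
#' the behavior trait theta_i is redrawn from its normal full conditional
#' (item residuals plus the prior cross terms with z_i). Participants are
#' conditionally independent and updated as a vectorized block per
#' region. Participants with no observed edges (or items) receive pure
#' prior-conditional draws, which is how held-out participants are
#' imputed.
#'
#' @param state A `model_state`.
#' @param conn A `connectivity_data`.
#' @param behav A `behavior_data`.
#' @param region_marginal_prior If TRUE, use only the 2 x 2 (region,
#'   trait) submatrix of Sigma for the z prior term.
#' @param reflection_moves If TRUE (default), precede the scan with a
#'   per-participant reflection Metropolis move proposing z_i -> -z_i.
#'   The bilinear likelihood is invariant under the flip, so the
#'   acceptance ratio involves only the prior cross term with theta_i;
#'   the move preserves the posterior exactly and lets the latent signs
#'   order across the two reflection modes, which region-by-region scans
#'   alone essentially never traverse.
#' @param rindex Optional precomputed `.region_index` result (internal
#'   speed-up for [run_chain()]).
#' @return The updated `model_state`.
#' @export
update_latents <- function(state, conn, behav, region_marginal_prior = FALSE,
                           reflection_moves = TRUE, rindex = NULL) {
  .check_state_conn(state, conn)
  .check_state_behav(state, behav)
  V <- conn$n_regions
  K <- V + 1L
  part <- partition_precision(state$Sigma)  # errors if Sigma not PD
  Q <- part$Q
  inv_s2 <- 1 / state$sigma2
  all_obs <- all(conn$mask)
  B <- conn$edges - as.numeric(conn$covariates %*% state$beta) - state$a
  if (!all_obs) B <- B * conn$mask
  Z <- state$Z
  theta <- state$theta
  N <- nrow(Z)
  ## item residual sums t_{i,p} = y - h'gamma - b_p (unit loadings)
  Tres <- (behav$outcomes - as.numeric(behav$covariates %*% state$gamma) -
             rep(state$b, each = N)) * behav$mask
  t_lin <- rowSums(Tres)
  n_p <- rowSums(behav$mask)
  inv_t2 <- 1 / state$tau2

  if (!region_marginal_prior) {
    out <- .latent_sweep_cpp(Z, theta, B, conn$pairs, Q, inv_s2, t_lin, n_p,
                             inv_t2, .mask_arg(conn, all_obs), all_obs,
                             isTRUE(reflection_moves))
    state$Z <- out$Z
    state$theta <- drop(out$theta)
    return(state)
  }

  ## reference variant: the z prior term uses only the 2 x 2 (region,
  ## trait) submatrix of Sigma, mirroring the printed full conditional
  if (is.null(rindex)) rindex <- .region_index(conn$pairs, V)
  if (reflection_moves) {
    log_r <- 2 * theta * drop(Z %*% Q[seq_len(V), K])
    flip <- log(stats::runif(N)) < log_r
    if (any(flip)) Z[flip, ] <- -Z[flip, , drop = FALSE]
  }
  if (all_obs) sumZ2 <- rowSums(Z * Z)
  for (u in seq_len(V)) {
    idx <- rindex[[u]]
    Znbr <- Z[, idx$nbr, drop = FALSE]
    if (all_obs) {
      data_prec <- (sumZ2 - Z[, u]^2) * inv_s2
    } else {
      Mnbr <- conn$mask[, idx$cols, drop = FALSE]
      data_prec <- rowSums(Znbr * Znbr * Mnbr) * inv_s2
    }
    data_lin <- rowSums(B[, idx$cols, drop = FALSE] * Znbr) * inv_s2
    S2 <- state$Sigma[c(u, K), c(u, K)]
    Qp <- solve(S2)
    prec <- data_prec + Qp[1L, 1L]
    mu <- (data_lin - Qp[1L, 2L] * theta) / prec
    z_new <- stats::rnorm(N, mu, sqrt(1 / prec))
    if (all_obs) sumZ2 <- sumZ2 + z_new^2 - Z[, u]^2
    Z[, u] <- z_new
  }
  prec_t <- n_p * inv_t2 + Q[K, K]
  lin_t <- t_lin * inv_t2 - drop(Z %*% Q[seq_len(V), K])
  theta <- stats::rnorm(N, lin_t / prec_t, sqrt(1 / prec_t))
  state$Z <- Z
  state$theta <- theta
  state
}

#' Gibbs update of the joint latent covariance Sigma
#'
#' Draws Sigma from its inverse-Wishart full conditional with scale
#' S0 + F'^T F' and degrees of freedom N + m0, where F' is the N x (V+1)
#' matrix with row i = (z_i', theta_i).
#'
#' @param state A `model_state`.
#' @param priors A `prior_spec`.
#' @return The updated `model_state`.
#' @export
update_Sigma <- function(state, priors) {
  F_ <- cbind(state$Z, state$theta)
  S_post <- priors$wishart_scale + crossprod(F_)
  ch <- tryCatch(chol(S_post), error = function(e) NULL)
  if (is.null(ch)) stop("inverse-Wishart scale matrix is not positive definite")
  nu <- nrow(F_) + priors$wishart_df
  Prec <- stats::rWishart(1L, nu, chol2inv(ch))[, , 1L]
  Sigma <- chol2inv(chol(Prec))
  state$Sigma <- (Sigma + t(Sigma)) / 2
  state
}

#' Align latent signs to a reference (reflection indeterminacy)
#'
#' The bilinear edge term is invariant to negating a participant's whole
#' latent vector, so the sign of z_i is only softly identified through
#' its prior cross term with theta_i. After burn-in the signs are fixed:
#' each row z_i is negated when its inner product with the corresponding
#' reference row is negative. A zero inner product keeps the current
#' sign.
#'
#' @param state A `model_state`.
#' @param reference_Z N x V reference matrix (the first post-burn-in draw).
#' @return The `model_state` with aligned `Z`.
#' @export
align_reflection <- function(state, reference_Z) {
  if (!all(dim(state$Z) == dim(reference_Z))) {
    stop("reference_Z must have the same dimensions as state$Z")
  }
  s <- rowSums(state$Z * reference_Z)
  flip <- s < 0
  if (any(flip)) state$Z[flip, ] <- -state$Z[flip, , drop = FALSE]
  state
}

#' Run one Gibbs chain
#'
#' Executes the update cycle (beta, a) -> sigma2 -> (gamma, b) -> tau2 ->
#' {Z, theta} -> Sigma for `n_iterations`, records the reference Z at the
#' first post-burn-in iteration and sign-aligns every later draw to it
#' before storage. Missing outcomes and missing edges are imputed by
#' posterior-predictive draws at every retained iteration; their running
#' means are returned as predictions.
#'
#' @param conn A `connectivity_data`.
#' @param behav A paired `behavior_data`.
#' @param priors A `prior_spec` (default: reference priors for V).
#' @param config A `sampler_config`.
#' @param init Optional starting `model_state` (default: drawn by
#'   [initialize_state()] with `config$seed`).
#' @return An object of class `posterior_samples` with elements
#'   `cross_cov` (draws x V matrix of the connectivity-behavior
#'   cross-covariance column of Sigma), `lambda_theta`, `sigma2_draws`,
#'   `tau2_draws`, `beta_draws`, `gamma_draws`, `latent_mean_Z`,
#'   `latent_mean_theta`, `y_pred`, `x_pred`, `reference_Z`,
#'   `final_state`, bookkeeping fields, and (if `store_latents`)
#'   `Z_draws`, `theta_draws`.
#' @export
run_chain <- function(conn, behav, priors = prior_spec(conn$n_regions),
                      config = sampler_config()) {
  if (conn$n_participants != behav$n_participants) {
    stop("connectivity has N = ", conn$n_participants,
         " but behavior has N = ", behav$n_participants)
  }
  state <- initialize_state(conn, behav, priors, config$seed)
  N <- conn$n_participants; V <- conn$n_regions; P <- behav$n_items
  K <- V + 1L
  rindex <- .region_index(conn$pairs, V)
  n_ret <- (config$n_iterations - config$burn_in) %/% config$thinning
  cross_cov <- matrix(NA_real_, n_ret, V)
  lambda_theta <- numeric(n_ret)
  sigma2_draws <- numeric(n_ret)
  tau2_draws <- numeric(n_ret)
  beta_draws <- matrix(NA_real_, n_ret, length(state$beta))
  gamma_draws <- matrix(NA_real_, n_ret, length(state$gamma))
  Zsum <- matrix(0, N, V); thetasum <- numeric(N)
  miss_y <- !behav$mask
  any_miss_y <- any(miss_y)
  y_acc <- if (any_miss_y) matrix(0, N, P)
  ## participants with no observed items: their trait posterior is
  ## reflection-bimodal (the sign is tied to the freely flipping latent
  ## row), so their imputations are drawn in the sign-aligned mode
  unlabeled <- rowSums(behav$mask) == 0L
  miss_x <- !conn$mask
  any_miss_x <- any(miss_x)
  x_acc <- if (any_miss_x) matrix(0, N, ncol(conn$edges))
  Z_draws <- if (config$store_latents) array(NA_real_, c(n_ret, N, V))
  theta_draws <- if (config$store_latents) matrix(NA_real_, n_ret, N)
  reference_Z <- NULL
  kept <- 0L

  for (it in seq_len(config$n_iterations)) {
    zz <- .bilinear(state$Z, conn$pairs)
    state <- update_connectivity_regression(state, conn, priors, zz = zz)
    state <- update_sigma2(state, conn, priors, zz = zz)
    state <- update_behavior_regression(state, behav, priors)
    state <- update_tau2(state, behav, priors)
    state <- update_latents(state, conn, behav,
                            region_marginal_prior = config$region_marginal_prior,
                            rindex = rindex)
    state <- update_Sigma(state, priors)

    bad <- c(beta = any(!is.finite(state$beta)),
             sigma2 = !is.finite(state$sigma2),
             gamma = any(!is.finite(state$gamma)),
             tau2 = !is.finite(state$tau2),
             Z = any(!is.finite(state$Z)),
             theta = any(!is.finite(state$theta)),
             Sigma = any(!is.finite(state$Sigma)))
    if (any(bad)) {
      stop("numerical blow-up at iteration ", it, " in parameter ",
           paste(names(bad)[bad], collapse = ", "))
    }
    if (config$verbose && it %% 100L == 0L) {
      message(sprintf("iter %d  logdens %.2f  sigma2 %.4f  tau2 %.4f", it,
                      joint_log_density(state, conn, behav),
                      state$sigma2, state$tau2))
    }

    if (it > config$burn_in) {
      if (is.null(reference_Z)) {
        ## reference draw for sign alignment: the STORED (not the
        ## evolving) states are aligned to it, so alignment never feeds
        ## back into the chain dynamics
        reference_Z <- state$Z
      }
      if ((it - config$burn_in) %% config$thinning == 0L && kept < n_ret) {
        kept <- kept + 1L
        cross_cov[kept, ] <- state$Sigma[seq_len(V), K]
        lambda_theta[kept] <- state$Sigma[K, K]
        sigma2_draws[kept] <- state$sigma2
        tau2_draws[kept] <- state$tau2
        beta_draws[kept, ] <- state$beta
        gamma_draws[kept, ] <- state$gamma
        ## sign-align a copy of the draw to the reference (never the
        ## evolving chain state itself)
        flip_rows <- rowSums(state$Z * reference_Z) < 0
        Zal <- state$Z
        if (any(flip_rows)) Zal[flip_rows, ] <- -Zal[flip_rows, , drop = FALSE]
        Zsum <- Zsum + Zal
        thetasum <- thetasum + state$theta
        if (any_miss_y) {
          ## for unlabeled rows, flipping z to the reference mode negates
          ## the conditional trait draw, so the aligned-mode draw is the
          ## sign-corrected state draw
          s_align <- ifelse(flip_rows, -1, 1)
          theta_imp <- ifelse(unlabeled, s_align * state$theta, state$theta)
          drift_y <- as.numeric(behav$covariates %*% state$gamma) + theta_imp
          mu_y <- outer(drift_y, rep(1, P)) + rep(state$b, each = N)
          y_acc[miss_y] <- y_acc[miss_y] + mu_y[miss_y] +
            stats::rnorm(sum(miss_y), sd = sqrt(state$tau2))
        }
        if (any_miss_x) {
          mu_x <- .edge_mean_matrix(state, conn)
          x_acc[miss_x] <- x_acc[miss_x] + mu_x[miss_x] +
            stats::rnorm(sum(miss_x), sd = sqrt(state$sigma2))
        }
        if (config$store_latents) {
          Z_draws[kept, , ] <- Zal
          theta_draws[kept, ] <- state$theta
        }
      }
    }
  }

  ## global reflection orientation: the two global modes (all latent
  ## rows negated, cross-covariance column mirrored) are exactly
  ## equiprobable, so draws are reported in the orientation whose net
  ## cross-covariance with the trait is positive. A single whole-sample
  ## mirror never changes which intervals exclude zero.
  if (sum(cross_cov) < 0) {
    cross_cov <- -cross_cov
    Zsum <- -Zsum
    if (config$store_latents) Z_draws <- -Z_draws
  }
  y_pred <- NULL
  if (any_miss_y) {
    y_pred <- matrix(NA_real_, N, P)
    y_pred[miss_y] <- y_acc[miss_y] / kept
  }
  x_pred <- NULL
  if (any_miss_x) {
    x_pred <- matrix(NA_real_, N, ncol(conn$edges))
    x_pred[miss_x] <- x_acc[miss_x] / kept
  }
  structure(list(
    cross_cov = cross_cov, lambda_theta = lambda_theta,
    sigma2_draws = sigma2_draws, tau2_draws = tau2_draws,
    beta_draws = beta_draws, gamma_draws = gamma_draws,
    latent_mean_Z = Zsum / kept, latent_mean_theta = thetasum / kept,
    y_pred = y_pred, x_pred = x_pred,
    Z_draws = Z_draws, theta_draws = theta_draws,
    reference_Z = reference_Z, final_state = state,
    region_labels = conn$region_labels,
    n_iterations = config$n_iterations, burn_in = config$burn_in,
    thinning = config$thinning, seed = config$seed, n_retained = kept
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", x$n_retained, "retained draws over",
      ncol(x$cross_cov), "regions (", x$n_iterations, "iterations, burn-in",
      x$burn_in, ", thinning", x$thinning, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Multi-start fitting with held-out selection
#'
#' Runs `config$n_starts` chains from distinct seeds (`config$seed`,
#' `config$seed + 1`, ...). Each chain is scored by the correlation
#' between held-out behavior outcomes (a random participant subset whose
#' outcomes are masked and imputed within the chain) and their
#' posterior-mean predictions; the best-scoring chain is refit on the
#' full data and returned.
#'
#' @param conn A `connectivity_data`.
#' @param behav A `behavior_data`.
#' @param priors A `prior_spec`.
#' @param config A `sampler_config` (`n_starts` chains).
#' @param holdout_fraction Fraction of participants held out for scoring,
#'   in (0, 0.5].
#' @return List with `state` (final `model_state` of the winning chain),
#'   `samples` (`posterior_samples` of the winning full-data chain) and
#'   `scores` (held-out correlation per start).
#' @export
multi_start_fit <- function(conn, behav, priors = prior_spec(conn$n_regions),
                            config = sampler_config(),
                            holdout_fraction = 0.2) {
  if (holdout_fraction <= 0 || holdout_fraction > 0.5) {
    stop("holdout_fraction must lie in (0, 0.5]")
  }
  N <- conn$n_participants
  set.seed(config$seed)
  n_hold <- max(2L, round(holdout_fraction * N))
  hold <- sample.int(N, n_hold)
  behav_masked <- behav
  behav_masked$mask[hold, ] <- FALSE
  behav_masked$outcomes[hold, ] <- 0
  scores <- rep(NA_real_, config$n_starts)
  errors <- character(0)
  for (s in seq_len(config$n_starts)) {
    cfg_s <- config
    cfg_s$seed <- config$seed + s - 1L
    res <- tryCatch(run_chain(conn, behav_masked, priors, cfg_s),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("start %d: %s", s, conditionMessage(res)))
      next
    }
    pred <- res$y_pred[hold, ]
    obs <- behav$outcomes[hold, ]
    obs[!behav$mask[hold, ]] <- NA
    ok <- is.finite(pred) & is.finite(obs)
    scores[s] <- if (sum(ok) >= 3L) stats::cor(pred[ok], obs[ok]) else NA_real_
  }
  if (all(is.na(scores))) {
    stop("all starts failed: ", paste(errors, collapse = "; "))
  }
  best <- which.max(scores)
  cfg_best <- config
  cfg_best$seed <- config$seed + best - 1L
  samples <- run_chain(conn, behav, priors, cfg_best)
  list(state = samples$final_state, samples = samples, scores = scores)
}
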