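# Full-conditional correctness. Each sampler step is checked against the
# closed-form posterior of a fixed tiny instance: the update is applied
# many times to the same incoming state and the empirical first two
# moments of the draws are compared with the analytic values (composite
# moments where one draw feeds the next within a step, via the laws of
# total expectation and variance).

test_that("initialization is deterministic and prior-shaped", {
  d <- tiny_data(N = 5L, V = 3L, P = 2L)
  pr <- prior_spec(3L)
  s1 <- initialize_state(d$conn, d$behav, pr, seed = 11L)
  s2 <- initialize_state(d$conn, d$behav, pr, seed = 11L)
  expect_identical(s1, s2)
  s3 <- initialize_state(d$conn, d$behav, pr, seed = 12L)
  expect_false(identical(s1$Z, s3$Z))
  expect_equal(s1$Sigma, diag(4L))
  expect_equal(s1$sigma2, 1)
  ## paired-N contract
  d2 <- tiny_data(N = 4L, V = 3L)
  expect_error(initialize_state(d$conn, d2$behav, pr, 1L), "N = ")
})

test_that("connectivity regression draws match the conjugate oracle", {
  ## N = 2, V = 2 (one edge each), Q = 1, everything else held fixed
  Z <- rbind(c(1, 2), c(-1, 0.5))
  zz <- Z[, 1L] * Z[, 2L]
  x <- c(1.5, -0.7); a_old <- c(0.3, -0.4); sigma2 <- 2
  conn <- connectivity_data(cbind(x), n_regions = 2L)
  st <- model_state(beta = 0, a = a_old, sigma2 = sigma2, gamma = 0, b = 0,
                    tau2 = 1, Z = Z, theta = c(0, 0), Sigma = diag(3L))
  pr <- prior_spec(2L)
  ## oracle: beta | rest is N(mB, vB); a_1 | beta is conjugate normal,
  ## so its marginal moments follow by total expectation/variance
  vB <- 1 / (1 + 2 / sigma2)
  mB <- vB * sum(x - zz - a_old) / sigma2
  prec_a <- 1 + 1 / sigma2
  E_a1 <- (x[1L] - zz[1L] - mB) / sigma2 / prec_a
  V_a1 <- 1 / prec_a + vB / (sigma2 * prec_a)^2

  set.seed(42)
  n_draw <- 10000L
  bs <- numeric(n_draw); as <- numeric(n_draw)
  for (k in seq_len(n_draw)) {
    up <- update_connectivity_regression(st, conn, pr)
    bs[k] <- up$beta; as[k] <- up$a[1L]
  }
  expect_lt(abs(mean(bs) - mB), 3 * sqrt(vB / n_draw))
  expect_lt(abs(var(bs) - vB), 3 * vB * sqrt(2 / n_draw))
  expect_lt(abs(mean(as) - E_a1), 3 * sqrt(V_a1 / n_draw))
  expect_lt(abs(var(as) - V_a1), 3 * V_a1 * sqrt(2 / n_draw))

  ## no-information limit: sigma2 -> Inf leaves the prior
  st_inf <- st; st_inf$sigma2 <- 1e12
  set.seed(43)
  bs_inf <- replicate(5000, update_connectivity_regression(st_inf, conn, pr)$beta)
  expect_lt(abs(mean(bs_inf)), 3 / sqrt(5000))
  expect_lt(abs(var(bs_inf) - 1), 3 * sqrt(2 / 5000))

  ## centered data: zero residuals give zero posterior mean for a
  conn0 <- connectivity_data(cbind(zz), n_regions = 2L)
  st0 <- st; st0$a <- c(0, 0)
  set.seed(44)
  a0 <- replicate(5000, update_connectivity_regression(st0, conn0, pr)$a[1L])
  expect_lt(abs(mean(a0)), 3 * sqrt(1 / 5000))
})

test_that("edge variance draws match the conjugate gamma oracle", {
  ## zero residuals with N*M = 2: precision ~ gamma(1.5, 0.5)
  Z <- rbind(c(1, 2), c(-1, 0.5))
  zz <- Z[, 1L] * Z[, 2L]
  conn <- connectivity_data(cbind(zz), n_regions = 2L)
  st <- model_state(beta = 0, a = c(0, 0), sigma2 = 1, gamma = 0, b = 0,
                    tau2 = 1, Z = Z, theta = c(0, 0), Sigma = diag(3L))
  pr <- prior_spec(2L)
  set.seed(45)
  prec <- replicate(10000, 1 / update_sigma2(st, conn, pr)$sigma2)
  expect_true(all(prec > 0))
  expect_lt(abs(mean(prec) - 3), 3 * sqrt(6 / 10000))        # gamma mean 1.5/0.5
  expect_lt(abs(var(prec) - 6), 3 * 6 * sqrt(2 / 10000) * 3) # gamma var 1.5/0.25

  ## consistency: true sigma2 = 2 recovered within 10% at N*M >= 10,000
  set.seed(46)
  N <- 100L; V <- 15L
  pairs <- edge_pairs(V)
  Zb <- matrix(rnorm(N * V), N)
  E <- Zb[, pairs[, "u"]] * Zb[, pairs[, "v"]] +
    matrix(rnorm(N * nrow(pairs), sd = sqrt(2)), N)
  connb <- connectivity_data(E, n_regions = V)
  stb <- model_state(beta = 0, a = rep(0, N), sigma2 = 1, gamma = 0, b = 0,
                     tau2 = 1, Z = Zb, theta = rep(0, N),
                     Sigma = diag(V + 1L))
  s2 <- update_sigma2(stb, connb, prior_spec(V))$sigma2
  expect_lt(abs(s2 - 2) / 2, 0.1)
})

test_that("behavior regression draws match the conjugate oracle", {
  ## P = 1, N = 3, theta = 0, covariate intercept only
  y <- c(1.0, -0.3, 0.6); b_old <- 0.5; tau2 <- 0.8
  behav <- behavior_data(cbind(y))
  st <- model_state(beta = 0, a = rep(0, 3), sigma2 = 1, gamma = 0,
                    b = b_old, tau2 = tau2, Z = matrix(0, 3, 2),
                    theta = rep(0, 3), Sigma = diag(3L))
  pr <- prior_spec(2L)
  vG <- 1 / (1 + 3 / tau2)
  mG <- vG * sum(y - b_old) / tau2
  prec_b <- 1 + 3 / tau2
  E_b <- (sum(y) - 3 * mG) / tau2 / prec_b
  V_b <- 1 / prec_b + (3 / tau2 / prec_b)^2 * vG
  set.seed(47)
  n_draw <- 10000L
  gs <- numeric(n_draw); bs <- numeric(n_draw)
  for (k in seq_len(n_draw)) {
    up <- update_behavior_regression(st, behav, pr)
    gs[k] <- up$gamma; bs[k] <- up$b
  }
  expect_lt(abs(mean(gs) - mG), 3 * sqrt(vG / n_draw))
  expect_lt(abs(var(gs) - vG), 3 * vG * sqrt(2 / n_draw))
  expect_lt(abs(mean(bs) - E_b), 3 * sqrt(V_b / n_draw))
  expect_lt(abs(var(bs) - V_b), 3 * V_b * sqrt(2 / n_draw))

  ## tau2 -> Inf limit recovers the standard-normal prior
  st_inf <- st; st_inf$tau2 <- 1e12
  set.seed(48)
  b_inf <- replicate(5000, update_behavior_regression(st_inf, behav, pr)$b)
  expect_lt(abs(mean(b_inf)), 3 / sqrt(5000))
  expect_lt(abs(var(b_inf) - 1), 3 * sqrt(2 / 5000))

  ## all-zero residuals shrink b toward 0
  behav0 <- behavior_data(cbind(c(0, 0, 0)))
  st0 <- st; st0$b <- 0
  set.seed(49)
  b0 <- replicate(5000, update_behavior_regression(st0, behav0, pr)$b)
  expect_lt(abs(mean(b0)), 3 * sqrt(1 / 5000))
})

test_that("item variance draws match the conjugate gamma oracle", {
  ## zero residuals, N*P = 3: precision ~ gamma(2, 0.5)
  behav <- behavior_data(cbind(c(0.5, 0.5, 0.5)))
  st <- model_state(beta = 0, a = rep(0, 3), sigma2 = 1, gamma = 0,
                    b = 0.5, tau2 = 1, Z = matrix(0, 3, 2),
                    theta = rep(0, 3), Sigma = diag(3L))
  pr <- prior_spec(2L)
  set.seed(50)
  prec <- replicate(10000, 1 / update_tau2(st, behav, pr)$tau2)
  expect_true(all(prec > 0))
  expect_lt(abs(mean(prec) - 4), 3 * sqrt(8 / 10000))
  expect_lt(abs(var(prec) - 8), 3 * 8 * sqrt(2 / 10000) * 3)

  ## consistency: tau2 = 0.5 within 10% at N*P = 10,000
  set.seed(51)
  N <- 10000L
  th <- rnorm(N)
  yb <- behavior_data(cbind(th + rnorm(N, sd = sqrt(0.5))))
  stb <- model_state(beta = 0, a = rep(0, N), sigma2 = 1, gamma = 0, b = 0,
                     tau2 = 1, Z = matrix(0, N, 2), theta = th,
                     Sigma = diag(3L))
  t2 <- update_tau2(stb, yb, prior_spec(2L))$tau2
  expect_lt(abs(t2 - 0.5) / 0.5, 0.1)
})

test_that("Sigma draws match the inverse-Wishart closed forms", {
  ## fixed F' with V = 2, N = 5: E[Sigma | F'] = (I + F'^T F') / (N + m0 - V - 2)
  set.seed(52)
  Z <- matrix(rnorm(10), 5L)
  th <- rnorm(5)
  st <- model_state(beta = 0, a = rep(0, 5), sigma2 = 1, gamma = 0, b = 0,
                    tau2 = 1, Z = Z, theta = th, Sigma = diag(3L))
  pr <- prior_spec(2L)    # m0 = V + 1 + 2 = 5
  S_post <- diag(3L) + crossprod(cbind(Z, th))
  oracle_mean <- S_post / (5 + 5 - 3 - 1)
  n_draw <- 10000L
  acc <- matrix(0, 3L, 3L); acc2 <- matrix(0, 3L, 3L)
  min_eig <- Inf
  for (k in seq_len(n_draw)) {
    S <- update_Sigma(st, pr)$Sigma
    min_eig <- min(min_eig,
                   eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    acc <- acc + S; acc2 <- acc2 + S^2
  }
  expect_gt(min_eig, 0)   # every draw symmetric positive definite
  emp_mean <- acc / n_draw
  emp_sd <- sqrt(pmax(acc2 / n_draw - emp_mean^2, 0))
  expect_true(all(abs(emp_mean - oracle_mean) < 3 * emp_sd / sqrt(n_draw) + 1e-12))

  ## large N: posterior mean approaches the sample covariance
  set.seed(53)
  Sig_true <- matrix(c(1, 0.5, 0.3, 0.5, 1, 0.2, 0.3, 0.2, 1), 3L)
  F_ <- matrix(rnorm(5000 * 3), 5000L) %*% chol(Sig_true)
  stN <- model_state(beta = 0, a = rep(0, 5000), sigma2 = 1, gamma = 0,
                     b = 0, tau2 = 1, Z = F_[, 1:2], theta = F_[, 3L],
                     Sigma = diag(3L))
  samp_cov <- crossprod(F_) / 5000
  post_mean <- Reduce(`+`, lapply(1:200, function(k) update_Sigma(stN, pr)$Sigma)) / 200
  expect_lt(norm(post_mean - samp_cov, "F") / norm(samp_cov, "F"), 0.05)
})

test_that("latent trait full conditional matches the decoupled oracle", {
  ## Lambda_ztheta = 0 and block-diagonal Sigma: theta's conditional is the
  ## plain Bayesian normal-mean posterior of the item residuals
  y <- c(1.2, 0.8, 1.0); tau2 <- 0.6; lam_t <- 0.7
  conn <- connectivity_data(matrix(rnorm(1), 1L, 1L), n_regions = 2L)
  behav <- behavior_data(matrix(y, 1L))
  st <- model_state(beta = 0, a = 0, sigma2 = 1, gamma = 0, b = rep(0, 3),
                    tau2 = tau2, Z = matrix(c(0.4, -0.2), 1L), theta = 0,
                    Sigma = diag(c(1, 1, lam_t)))
  prec <- 3 / tau2 + 1 / lam_t
  mu <- sum(y) / tau2 / prec
  set.seed(54)
  th <- replicate(10000, update_latents(st, conn, behav)$theta)
  expect_lt(abs(mean(th) - mu), 3 * sqrt(1 / prec / 10000))
  expect_lt(abs(var(th) - 1 / prec), 3 * (1 / prec) * sqrt(2 / 10000))
})

test_that("with no data weight repeated sweeps sample the joint prior", {
  ## sigma2, tau2 -> Inf: the stationary law of {Z, theta} is MVN(0, Sigma)
  Sig <- matrix(0.5, 3L, 3L); diag(Sig) <- 1
  conn <- connectivity_data(matrix(0.3, 1L, 1L), n_regions = 2L)
  behav <- behavior_data(matrix(0.5, 1L, 1L))
  st <- model_state(beta = 0, a = 0, sigma2 = 1e10, gamma = 0, b = 0,
                    tau2 = 1e10, Z = matrix(c(0.1, 0.1), 1L), theta = 0.1,
                    Sigma = Sig)
  set.seed(55)
  draws <- matrix(NA_real_, 6000L, 3L)
  cur <- st
  for (k in 1:6000) {
    cur <- update_latents(cur, conn, behav)
    draws[k, ] <- c(cur$Z[1L, ], cur$theta)
  }
  emp <- crossprod(draws) / nrow(draws)
  expect_lt(max(abs(emp - Sig)), 0.1)
  expect_lt(max(abs(colMeans(draws))), 0.1)
})

test_that("reflection alignment is an involution that preserves the likelihood", {
  d <- tiny_data(N = 4L, V = 3L, seed = 20L)
  st <- tiny_state(N = 4L, V = 3L, seed = 21L)
  ref <- st$Z
  ## already aligned: identity
  expect_identical(align_reflection(st, ref)$Z, st$Z)
  ## negate every row, align back: exact recovery
  st_neg <- st; st_neg$Z <- -st$Z
  expect_equal(align_reflection(st_neg, ref)$Z, st$Z)
  ## the connectivity mean is invariant under any row flip; the joint
  ## density changes only through the prior cross term with theta
  st$Sigma <- diag(4L) * 0.8 + 0.2
  st_flip <- st; st_flip$Z[2L, ] <- -st_flip$Z[2L, ]
  for (i in 1:4) {
    expect_equal(connectivity_mean(st_flip, d$conn, i),
                 connectivity_mean(st, d$conn, i))
  }
  Q <- solve(st$Sigma)
  cross_term <- function(z, th) -0.5 * (2 * th * sum(Q[4L, 1:3] * z))
  delta_prior <- cross_term(st_flip$Z[2L, ], st$theta[2L]) -
    cross_term(st$Z[2L, ], st$theta[2L])
  expect_equal(joint_log_density(st_flip, d$conn, d$behav) -
                 joint_log_density(st, d$conn, d$behav),
               delta_prior, tolerance = 1e-9)
})

test_that("chain bookkeeping, determinism and retained counts", {
  d <- tiny_data(N = 6L, V = 3L, P = 1L, seed = 23L)
  pr <- prior_spec(3L)
  cfg <- sampler_config(n_iterations = 80L, burn_in = 20L, thinning = 3L,
                        seed = 9L)
  s1 <- run_chain(d$conn, d$behav, pr, cfg)
  expect_equal(s1$n_retained, (80L - 20L) %/% 3L)
  expect_equal(nrow(s1$cross_cov), s1$n_retained)
  s2 <- run_chain(d$conn, d$behav, pr, cfg)
  expect_identical(s1$cross_cov, s2$cross_cov)
  expect_identical(s1$latent_mean_Z, s2$latent_mean_Z)
  cfg2 <- sampler_config(n_iterations = 80L, burn_in = 20L, thinning = 3L,
                         seed = 10L)
  s3 <- run_chain(d$conn, d$behav, pr, cfg2)
  expect_false(identical(s1$cross_cov, s3$cross_cov))
  ## invalid configurations are rejected up front
  expect_error(sampler_config(n_iterations = 100L, burn_in = 100L), "burn_in")
  expect_error(sampler_config(n_iterations = 12L, burn_in = 10L), "10 draws")
})

test_that("multi-start selection scores every start and picks a winner", {
  sim <- simulate_dataset(simulation_config(n_participants = 120L,
                                            n_regions = 6L, snr = 1,
                                            signal_proportion = 0.5,
                                            seed = 60L))
  pr <- prior_spec(6L)
  cfg <- sampler_config(n_iterations = 400L, burn_in = 150L, seed = 2L,
                        n_starts = 2L)
  fit <- multi_start_fit(sim$connectivity, sim$behavior, pr, cfg,
                         holdout_fraction = 0.25)
  expect_length(fit$scores, 2L)
  expect_true(all(is.finite(fit$scores)))
  expect_s3_class(fit$samples, "posterior_samples")
  expect_s3_class(fit$state, "model_state")
  ## the returned chain is the full-data refit of the best-scoring start
  best <- which.max(fit$scores)
  cfg_best <- cfg; cfg_best$seed <- cfg$seed + best - 1L
  refit <- run_chain(sim$connectivity, sim$behavior, pr, cfg_best)
  expect_identical(fit$samples$cross_cov, refit$cross_cov)
  ## single start reduces to a plain chain with the same seed
  cfg1 <- sampler_config(n_iterations = 400L, burn_in = 150L, seed = 2L,
                         n_starts = 1L)
  fit1 <- multi_start_fit(sim$connectivity, sim$behavior, pr, cfg1,
                          holdout_fraction = 0.25)
  plain <- run_chain(sim$connectivity, sim$behavior, pr, cfg1)
  expect_identical(fit1$samples$cross_cov, plain$cross_cov)
  expect_error(multi_start_fit(sim$connectivity, sim$behavior, pr, cfg,
                               holdout_fraction = 0.9), "holdout_fraction")
})

test_that("cross-covariance RMSE decreases with sample size", {
  rmse_at <- function(N) {
    mean(vapply(1:3, function(r) {
      s <- simulate_dataset(simulation_config(n_participants = N,
                                              n_regions = 10L, snr = 1,
                                              signal_proportion = 0.2,
                                              seed = 700L + 10L * r))
      f <- run_chain(s$connectivity, s$behavior, prior_spec(10L),
                     sampler_config(n_iterations = 800L, burn_in = 300L,
                                    seed = r))
      est <- colMeans(f$cross_cov)
      sqrt(mean((est - s$truth$true_Sigma[1:10, 11L])^2))
    }, numeric(1)))
  }
  r250 <- rmse_at(250L); r500 <- rmse_at(500L); r1000 <- rmse_at(1000L)
  expect_true(r250 > r500)
  expect_true(r500 > r1000)
})
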