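# Out-of-sample prediction machinery: correlation metric, the mean
# baseline, the latent-position regression, and the missing-data
# imputation path through the sampler.

test_that("the correlation metric matches closed forms and guards edge cases", {
  expect_equal(prediction_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(prediction_correlation(c(1, 2, 3), c(-1, -2, -3)), -1)
  ## hand value for (1,2,3) vs (1,2,4)
  expect_equal(prediction_correlation(c(1, 2, 3), c(1, 2, 4)),
               cov(c(1, 2, 3), c(1, 2, 4)) / (sd(c(1, 2, 3)) * sd(c(1, 2, 4))))
  expect_equal(prediction_correlation(c(1, 2, 3), c(1, 2, 4)), 0.98198051,
               tolerance = 1e-7)
  ## zero variance warns and returns NA, never silent 0
  expect_warning(r <- prediction_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(r))
  expect_error(prediction_correlation(1:2, 1:2), "3 finite")
  expect_error(prediction_correlation(1:4, 1:3), "lengths differ")
})

test_that("the average baseline is the entry-wise training mean", {
  m <- sym_from_upper(3L, c(0, 1, 2))
  m2 <- sym_from_upper(3L, c(1, 3, 2))
  conn <- connectivity_data(list(m, m2, m))
  ## identical matrices reproduce themselves
  avg1 <- average_baseline(conn, train_ids = c(1L, 3L))
  expect_equal(avg1[1L, 2L], m[1L, 2L])
  ## two matrices with entry 0 and 1 average to 0.5
  avg2 <- average_baseline(conn, train_ids = c(1L, 2L))
  expect_equal(avg2[1L, 2L], 0.5)
  expect_equal(avg2, t(avg2))
  ## streaming-mean oracle on random matrices
  set.seed(77)
  E <- matrix(rnorm(60), 10L)
  connr <- connectivity_data(E, n_regions = 4L)
  avg <- average_baseline(connr)
  run <- rep(0, 6)
  for (i in 1:10) run <- run + (E[i, ] - run) / i
  expect_equal(avg[connr$pairs], run, tolerance = 1e-12)
})

test_that("latent-position regression recovers a perfect predictor", {
  ## one significant region whose latent column equals the outcome
  N <- 30L
  set.seed(80)
  y <- rnorm(N)
  Zm <- cbind(y, matrix(rnorm(N * 2), N))
  samples <- structure(list(latent_mean_Z = Zm,
                            region_labels = c("r1", "r2", "r3")),
                       class = "posterior_samples")
  report <- structure(data.frame(region = c("r1", "r2", "r3"),
                                 posterior_mean = c(0.9, 0, 0),
                                 ci_low = c(0.8, -0.1, -0.1),
                                 ci_high = c(1, 0.1, 0.1),
                                 significant = c(TRUE, FALSE, FALSE)),
                      class = c("biomarker_report", "data.frame"))
  behav <- behavior_data(cbind(y))
  test_ids <- 25:30
  res <- predict_behavior_z(samples, report, behav, test_ids)
  expect_equal(res$predictions, y[test_ids], tolerance = 1e-10)
  expect_equal(unname(res$coefficients), c(0, 1), tolerance = 1e-10)
  expect_equal(res$selected_regions, 1L)

  ## least squares matches the brute-force normal-equations solve
  report2 <- report; report2$significant <- c(TRUE, TRUE, FALSE)
  y2 <- y + rnorm(N, sd = 0.3)
  behav2 <- behavior_data(cbind(y2))
  res2 <- predict_behavior_z(samples, report2, behav2, test_ids)
  train <- setdiff(seq_len(N), test_ids)
  X <- cbind(1, Zm[train, 1:2])
  beta_ne <- solve(crossprod(X), crossprod(X, y2[train]))
  expect_equal(unname(res2$coefficients), unname(drop(beta_ne)), tolerance = 1e-8)

  ## jointly flipping a region's sign in train and test leaves predictions
  ## unchanged (the slope flips)
  samples_f <- samples
  samples_f$latent_mean_Z[, 1L] <- -samples_f$latent_mean_Z[, 1L]
  res_f <- predict_behavior_z(samples_f, report2, behav2, test_ids)
  expect_equal(res_f$predictions, res2$predictions, tolerance = 1e-10)
  expect_equal(unname(res_f$coefficients[2L]),
               -unname(res2$coefficients[2L]), tolerance = 1e-10)

  ## zero significant regions: training-mean fallback with a warning
  report0 <- report; report0$significant <- rep(FALSE, 3L)
  expect_warning(res0 <- predict_behavior_z(samples, report0, behav, test_ids),
                 "training outcome mean")
  expect_equal(res0$predictions, rep(mean(y[train]), length(test_ids)))
})

test_that("split specification is disjoint, exhaustive and reproducible", {
  sp <- split_spec(50L, n_repeats = 4L, test_size = 10L, seed = 5L)
  expect_length(sp$splits, 4L)
  for (s in sp$splits) {
    expect_length(s, 10L)
    expect_length(intersect(s, setdiff(1:50, s)), 0L)
    expect_setequal(union(s, setdiff(1:50, s)), 1:50)
  }
  sp2 <- split_spec(50L, n_repeats = 4L, test_size = 10L, seed = 5L)
  expect_identical(sp, sp2)
  expect_error(split_spec(10L, test_size = 100L), "smaller")
})

test_that("held-out imputation respects the test masks and hygiene", {
  sim <- simulate_dataset(simulation_config(n_participants = 60L,
                                            n_regions = 5L, snr = 1,
                                            signal_proportion = 0.4,
                                            seed = 81L))
  cfg <- sampler_config(n_iterations = 120L, burn_in = 40L, seed = 6L)
  test_ids <- 51:60
  res <- predict_behavior_theta(sim$connectivity, sim$behavior, test_ids,
                                prior_spec(5L), cfg)
  expect_equal(dim(res$predictions), c(10L, 1L))
  expect_true(all(is.finite(res$predictions)))
  ## training-phase hygiene: replacing test outcomes by sentinels leaves
  ## every training-phase draw bit-identical
  behav_s <- sim$behavior
  behav_s$outcomes[test_ids, ] <- 1e6
  ## constant sentinel outcomes make the reported correlation undefined,
  ## which warns; only the draws matter here
  res_s <- suppressWarnings(
    predict_behavior_theta(sim$connectivity, behav_s, test_ids,
                           prior_spec(5L), cfg))
  expect_identical(res$samples$cross_cov, res_s$samples$cross_cov)
  expect_identical(res$samples$latent_mean_Z, res_s$samples$latent_mean_Z)
  expect_identical(res$predictions, res_s$predictions)
  ## test participant with no observed edges errors
  conn_bad <- sim$connectivity
  conn_bad$mask[51L, ] <- FALSE
  expect_error(predict_behavior_theta(conn_bad, sim$behavior, test_ids,
                                      prior_spec(5L), cfg),
               "no observed edges")
})

test_that("connectivity prediction returns labeled symmetric matrices", {
  sim <- simulate_dataset(simulation_config(n_participants = 60L,
                                            n_regions = 6L, snr = 1,
                                            signal_proportion = 0.5,
                                            seed = 82L))
  cfg <- sampler_config(n_iterations = 160L, burn_in = 40L, seed = 7L)
  test_ids <- 55:60
  res <- predict_connectivity(sim$connectivity, sim$behavior, test_ids,
                              prior_spec(6L), cfg)
  expect_length(res$predictions, 6L)
  m <- res$predictions[[1L]]
  expect_equal(dim(m), c(6L, 6L))
  expect_equal(m, t(m))
  expect_true(all(is.na(diag(m))))
  ## top-k restriction returns a k x k matrix labeled by the report's top k
  rep_ <- summarize_covariances(res$samples)
  res5 <- predict_connectivity(sim$connectivity, sim$behavior, test_ids,
                               prior_spec(6L), cfg, top_k = 5L, report = rep_)
  m5 <- res5$predictions[[1L]]
  expect_equal(dim(m5), c(5L, 5L))
  top5 <- sort(order(abs(rep_$posterior_mean), decreasing = TRUE)[1:5])
  expect_equal(res5$regions, top5)
  expect_equal(rownames(m5), as.character(top5))
  ## behavior entirely missing for a test participant errors
  behav_bad <- sim$behavior
  behav_bad$mask[55L, ] <- FALSE
  expect_error(predict_connectivity(sim$connectivity, behav_bad, test_ids,
                                    prior_spec(6L), cfg),
               "no observed behavior")
})
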