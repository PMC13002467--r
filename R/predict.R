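# Out-of-sample prediction. Both directions reuse the semi-supervised
# missing-data machinery of the sampler: held-out quantities enter the
# chain as masked entries and are imputed by posterior-predictive draws
# at every retained iteration. A second behavior predictor regresses
# training outcomes on the estimated latent positions of significant
# regions. The group-mean connectivity matrix is the comparison baseline.

#' Train/test split specification
#'
#' The evaluation protocol: `n_repeats` random splits, each holding out
#' `test_size` participants.
#'
#' @param n_total Total participant count.
#' @param n_repeats Number of random splits (default 10).
#' @param test_size Held-out participants per split (default 100).
#' @param seed Integer RNG seed.
#' @return An object of class `split_spec`: list of `n_repeats` integer
#'   vectors of test indices.
#' @export
split_spec <- function(n_total, n_repeats = 10L, test_size = 100L, seed = 1L) {
  n_total <- as.integer(n_total)
  test_size <- as.integer(test_size)
  if (test_size >= n_total) stop("test_size must be smaller than n_total")
  set.seed(as.integer(seed))
  splits <- lapply(seq_len(n_repeats), function(r) sort(sample.int(n_total, test_size)))
  structure(list(splits = splits, n_total = n_total,
                 n_repeats = as.integer(n_repeats), test_size = test_size,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Predict behavior from connectivity via the latent trait
#'
#' Test participants enter the MCMC with their outcomes treated as
#' missing: their latent positions are informed by their observed
#' connectivity, their traits by the joint prior, and each missing y_i is
#' drawn from its posterior predictive at every retained iteration. The
#' prediction is the posterior mean of those draws.
#'
#' @param conn A `connectivity_data` covering train and test participants.
#' @param behav A `behavior_data` with observed outcomes for everyone
#'   (test outcomes are masked internally, never seen by the sampler).
#' @param test_ids Integer indices of the test participants.
#' @param priors A `prior_spec`.
#' @param config A `sampler_config`.
#' @return List with `predictions` (test x P matrix), `observed`,
#'   `correlation` (Pearson, pooled over test entries) and `samples`.
#' @export
predict_behavior_theta <- function(conn, behav, test_ids,
                                   priors = prior_spec(conn$n_regions),
                                   config = sampler_config()) {
  test_ids <- sort(as.integer(test_ids))
  if (any(test_ids < 1L | test_ids > conn$n_participants)) {
    stop("test_ids out of range")
  }
  no_edges <- rowSums(conn$mask[test_ids, , drop = FALSE]) == 0L
  if (any(no_edges)) {
    stop("test participants with no observed edges: ",
         paste(test_ids[no_edges], collapse = ", "))
  }
  behav_masked <- behav
  behav_masked$mask[test_ids, ] <- FALSE
  behav_masked$outcomes[test_ids, ] <- 0
  samples <- run_chain(conn, behav_masked, priors, config)
  pred <- samples$y_pred[test_ids, , drop = FALSE]
  obs <- behav$outcomes[test_ids, , drop = FALSE]
  obs[!behav$mask[test_ids, , drop = FALSE]] <- NA
  list(predictions = pred, observed = obs,
       correlation = prediction_correlation(pred, obs),
       samples = samples)
}

#' Predict behavior from estimated latent positions of significant regions
#'
#' Implements the regression-based predictor: (1) select significant
#' regions from the biomarker report; (2) split the fitted posterior-mean
#' latent positions into train and test rows; (3) fit ordinary least
#' squares of the training outcomes on the training positions of the
#' selected regions; (4) predict test outcomes from the fitted
#' coefficients. With zero significant regions the training outcome mean
#' is predicted, with a warning.
#'
#' @param samples A `posterior_samples` fitted on all participants with
#'   test outcomes masked (e.g. the `samples` element of
#'   [predict_behavior_theta()]).
#' @param report A `biomarker_report` from the same fit.
#' @param behav The `behavior_data` with observed outcomes.
#' @param test_ids Integer indices of the test participants.
#' @param item Behavior item to predict (default 1).
#' @return List with `predictions`, `observed`, `correlation`,
#'   `selected_regions`, `coefficients`.
#' @export
predict_behavior_z <- function(samples, report, behav, test_ids, item = 1L) {
  stopifnot(inherits(samples, "posterior_samples"),
            inherits(report, "biomarker_report"))
  test_ids <- sort(as.integer(test_ids))
  train_ids <- setdiff(seq_len(nrow(samples$latent_mean_Z)), test_ids)
  sel <- which(report$significant)
  y_train <- behav$outcomes[train_ids, item]
  ok <- behav$mask[train_ids, item]
  obs <- behav$outcomes[test_ids, item]
  obs[!behav$mask[test_ids, item]] <- NA
  if (length(sel) == 0L) {
    warning("no significant regions; predicting the training outcome mean")
    mu <- mean(y_train[ok])
    pred <- rep(mu, length(test_ids))
    return(list(predictions = pred, observed = obs,
                correlation = NA_real_, selected_regions = integer(0),
                coefficients = NULL))
  }
  Ztr <- samples$latent_mean_Z[train_ids, sel, drop = FALSE]
  Zte <- samples$latent_mean_Z[test_ids, sel, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, Ztr[ok, , drop = FALSE]), y_train[ok])
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  pred <- drop(cbind(1, Zte) %*% coefs)
  list(predictions = pred, observed = obs,
       correlation = prediction_correlation(pred, obs),
       selected_regions = sel, coefficients = coefs)
}

#' Predict connectivity from behavior
#'
#' Test participants enter the MCMC with all their edges treated as
#' missing: their traits are informed by their observed outcomes, their
#' latent positions are drawn from the joint latent conditional given the
#' trait, and each missing edge is drawn from its posterior predictive at
#' every retained iteration. The prediction is the posterior-mean matrix.
#' Optionally the returned matrices are restricted to the top-k regions
#' of a biomarker report (ranked by |posterior mean|).
#'
#' @param conn A `connectivity_data` covering train and test participants
#'   (test edges are masked internally).
#' @param behav A `behavior_data` with observed outcomes.
#' @param test_ids Integer indices of the test participants.
#' @param priors A `prior_spec`.
#' @param config A `sampler_config`.
#' @param top_k Optional number of top biomarker regions to restrict to.
#' @param report Required when `top_k` is given.
#' @return List with `predictions` (list of V x V, or k x k, matrices,
#'   one per test participant), `observed` (same layout), `correlation`
#'   (pooled over test entries), `regions` (region indices used) and
#'   `samples`.
#' @export
predict_connectivity <- function(conn, behav, test_ids,
                                 priors = prior_spec(conn$n_regions),
                                 config = sampler_config(),
                                 top_k = NULL, report = NULL) {
  test_ids <- sort(as.integer(test_ids))
  if (any(test_ids < 1L | test_ids > conn$n_participants)) {
    stop("test_ids out of range")
  }
  no_items <- rowSums(behav$mask[test_ids, , drop = FALSE]) == 0L
  if (any(no_items)) {
    stop("test participants with no observed behavior: ",
         paste(test_ids[no_items], collapse = ", "))
  }
  conn_masked <- conn
  conn_masked$mask[test_ids, ] <- FALSE
  conn_masked$edges[test_ids, ] <- 0
  samples <- run_chain(conn_masked, behav, priors, config)
  regions <- seq_len(conn$n_regions)
  if (!is.null(top_k)) {
    if (is.null(report)) stop("top_k restriction requires a biomarker report")
    regions <- order(abs(report$posterior_mean), decreasing = TRUE)[seq_len(top_k)]
  }
  keep <- conn$pairs[, "u"] %in% regions & conn$pairs[, "v"] %in% regions
  sub_pairs <- conn$pairs[keep, , drop = FALSE]
  ridx <- match(seq_len(conn$n_regions), sort(regions))
  to_mat <- function(vals_keep) {
    k <- length(regions)
    m <- matrix(NA_real_, k, k,
                dimnames = rep(list(conn$region_labels[sort(regions)]), 2L))
    iu <- ridx[sub_pairs[, "u"]]; iv <- ridx[sub_pairs[, "v"]]
    m[cbind(iu, iv)] <- vals_keep
    m[cbind(iv, iu)] <- vals_keep
    m
  }
  pred_list <- lapply(test_ids, function(i) to_mat(samples$x_pred[i, keep]))
  obs_list <- lapply(test_ids, function(i) {
    vals <- conn$edges[i, keep]
    vals[!conn$mask[i, keep]] <- NA
    to_mat(vals)
  })
  pred_vec <- unlist(lapply(test_ids, function(i) samples$x_pred[i, keep]))
  obs_vec <- unlist(lapply(test_ids, function(i) {
    vals <- conn$edges[i, keep]; vals[!conn$mask[i, keep]] <- NA; vals
  }))
  names(pred_list) <- names(obs_list) <- conn$participant_ids[test_ids]
  list(predictions = pred_list, observed = obs_list,
       correlation = prediction_correlation(pred_vec, obs_vec),
       regions = sort(regions), samples = samples)
}

#' Entry-wise mean connectivity baseline
#'
#' The group-level baseline predictor: the entry-wise sample mean of the
#' training participants' connectivity matrices, used as the prediction
#' for every test participant.
#'
#' @param conn A `connectivity_data`.
#' @param train_ids Optional participant indices (default: all).
#' @return V x V symmetric matrix with `NA` diagonal.
#' @export
average_baseline <- function(conn, train_ids = NULL) {
  stopifnot(inherits(conn, "connectivity_data"))
  if (is.null(train_ids)) train_ids <- seq_len(conn$n_participants)
  if (length(train_ids) < 1L) stop("need at least one training participant")
  E <- conn$edges[train_ids, , drop = FALSE]
  E[!conn$mask[train_ids, , drop = FALSE]] <- NA
  mu <- colMeans(E, na.rm = TRUE)
  V <- conn$n_regions
  m <- matrix(NA_real_, V, V,
              dimnames = list(conn$region_labels, conn$region_labels))
  m[conn$pairs] <- mu
  m[conn$pairs[, c(2L, 1L)]] <- mu
  m
}

#' Repeated-split out-of-sample evaluation protocol
#'
#' The evaluation protocol of the prediction study: for each of the
#' splits in a [split_spec()], refit the model with the held-out
#' participants' target side masked, predict it, and record the
#' correlation with the held-out truth. Per-repeat correlations are
#' summarized by median and quartiles.
#'
#' @param conn A `connectivity_data`.
#' @param behav A `behavior_data`.
#' @param splits A `split_spec`.
#' @param mode One of `"theta"` (behavior from connectivity via the
#'   trait), `"z"` (behavior via the latent-position regression) or
#'   `"connectivity"` (connectivity from behavior).
#' @param priors A `prior_spec`.
#' @param config A `sampler_config` (per-repeat seeds are derived from
#'   `config$seed`).
#' @return List with `correlations` (one per repeat) and `summary`
#'   (named vector: median, q25, q75).
#' @export
prediction_protocol <- function(conn, behav, splits, mode = c("theta", "z", "connectivity"),
                                priors = prior_spec(conn$n_regions),
                                config = sampler_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(splits, "split_spec"))
  cors <- vapply(seq_along(splits$splits), function(r) {
    ids <- splits$splits[[r]]
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    if (mode == "theta") {
      predict_behavior_theta(conn, behav, ids, priors, cfg)$correlation
    } else if (mode == "z") {
      th <- predict_behavior_theta(conn, behav, ids, priors, cfg)
      rep_ <- summarize_covariances(th$samples)
      predict_behavior_z(th$samples, rep_, behav, ids)$correlation
    } else {
      predict_connectivity(conn, behav, ids, priors, cfg)$correlation
    }
  }, numeric(1))
  list(correlations = cors,
       summary = c(median = stats::median(cors),
                   q25 = unname(stats::quantile(cors, 0.25)),
                   q75 = unname(stats::quantile(cors, 0.75))))
}

#' Pearson correlation between predicted and observed values
#'
#' Used as the out-of-sample accuracy metric in both prediction
#' directions; matrices are compared over their vectorized u < v entries.
#' Non-finite pairs are dropped. Zero variance on either side yields `NA`
#' with a warning, never a silent 0.
#'
#' @param predicted,observed Numeric vectors or matrices of equal size.
#' @return Pearson correlation in [-1, 1], or `NA` if undefined.
#' @export
prediction_correlation <- function(predicted, observed) {
  p <- as.numeric(predicted); o <- as.numeric(observed)
  if (length(p) != length(o)) stop("predicted and observed lengths differ")
  ok <- is.finite(p) & is.finite(o)
  if (sum(ok) < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(p[ok]) == 0 || stats::sd(o[ok]) == 0) {
    warning("zero variance in predicted or observed values; correlation undefined")
    return(NA_real_)
  }
  stats::cor(p[ok], o[ok])
}
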