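# Comparison methods of the simulation study. All three consume the same
# vectorized edge representation, so benchmark comparisons against the
# joint model are seed- and split-matched.

#' Vectorized edge feature matrix
#'
#' The N x M matrix of unique pairwise edges (u < v, row-major pair
#' order) used by all baseline methods, with the column-to-pair map.
#'
#' @param conn A `connectivity_data`.
#' @return An object of class `edge_feature_matrix` with elements
#'   `features` (N x M), `index_map` (M x 2 matrix of (u, v)), and
#'   `n_regions`.
#' @export
edge_feature_matrix <- function(conn) {
  stopifnot(inherits(conn, "connectivity_data"))
  X <- conn$edges
  X[!conn$mask] <- NA
  structure(list(features = X, index_map = conn$pairs,
                 n_regions = conn$n_regions), class = "edge_feature_matrix")
}

#' Connectome-based predictive modeling (CPM)
#'
#' Correlates every vectorized edge with the training outcome, keeps
#' edges with two-sided p below `p_threshold`, splits them into
#' positively and negatively correlated sets, forms per-participant sum
#' scores over each set, fits a linear model of the outcome on the two
#' scores, and applies it to the test features. If no edge passes the
#' threshold, the training outcome mean is predicted with a warning.
#'
#' @param train_features `edge_feature_matrix` (or N x M matrix) for the
#'   training participants.
#' @param train_outcome Numeric training outcome vector.
#' @param test_features Features for the test participants.
#' @param p_threshold Two-sided edge-selection p-value threshold
#'   (default 0.01).
#' @return List with `predictions`, `selected_pos`, `selected_neg`
#'   (column indices), `selected_regions` (regions with >= 1 selected
#'   incident edge), `p_values`.
#' @export
cpm_fit_predict <- function(train_features, train_outcome, test_features,
                            p_threshold = 0.01) {
  Xtr <- if (inherits(train_features, "edge_feature_matrix")) {
    train_features$features
  } else as.matrix(train_features)
  map <- if (inherits(train_features, "edge_feature_matrix")) {
    train_features$index_map
  } else NULL
  Xte <- if (inherits(test_features, "edge_feature_matrix")) {
    test_features$features
  } else as.matrix(test_features)
  y <- as.numeric(train_outcome)
  n <- length(y)
  if (n <= 10L) stop("CPM needs more than 10 training participants")
  if (stats::sd(y) == 0) stop("training outcome has zero variance")
  r <- suppressWarnings(as.numeric(stats::cor(Xtr, y)))
  ## two-sided p from the t transform of the Pearson correlation
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pv[!is.finite(pv)] <- 1
  sel_pos <- which(pv < p_threshold & r > 0)
  sel_neg <- which(pv < p_threshold & r < 0)
  if (length(sel_pos) + length(sel_neg) == 0L) {
    warning("no edge passed the CPM threshold; predicting the training mean")
    preds <- rep(mean(y), nrow(Xte))
  } else {
    score <- function(X) {
      sp <- if (length(sel_pos)) rowSums(X[, sel_pos, drop = FALSE]) else rep(0, nrow(X))
      sn <- if (length(sel_neg)) rowSums(X[, sel_neg, drop = FALSE]) else rep(0, nrow(X))
      cbind(pos = sp, neg = sn)
    }
    str_ <- score(Xtr)
    keep <- c(TRUE, apply(str_, 2L, stats::sd) > 0)
    fit <- stats::lm.fit(cbind(1, str_)[, keep, drop = FALSE], y)
    co <- fit$coefficients; co[is.na(co)] <- 0
    preds <- drop(cbind(1, score(Xte))[, keep, drop = FALSE] %*% co)
  }
  selected_regions <- integer(0)
  if (!is.null(map)) {
    sel <- c(sel_pos, sel_neg)
    selected_regions <- sort(unique(as.integer(map[sel, ])))
  }
  list(predictions = preds, selected_pos = sel_pos, selected_neg = sel_neg,
       selected_regions = selected_regions, p_values = pv)
}

#' Lasso edge selection
#'
#' L1-penalized linear regression of the outcome on the full edge
#' matrix; the penalty minimizes 10-fold cross-validated mean squared
#' error. Selected edges are the nonzero coefficients at that penalty; a
#' region is flagged when any incident edge is selected. Coefficients
#' are not debiased.
#'
#' @param train_features `edge_feature_matrix` (or N x M matrix).
#' @param train_outcome Numeric training outcome vector (N >= 20).
#' @param seed Integer seed for the cross-validation folds.
#' @return List with `selected_edges` (column indices),
#'   `selected_regions`, `coefficients`, `lambda`.
#' @export
lasso_select <- function(train_features, train_outcome, seed = 1L) {
  X <- if (inherits(train_features, "edge_feature_matrix")) {
    train_features$features
  } else as.matrix(train_features)
  map <- if (inherits(train_features, "edge_feature_matrix")) {
    train_features$index_map
  } else NULL
  y <- as.numeric(train_outcome)
  if (length(y) < 20L) stop("lasso selection needs N >= 20")
  const <- apply(X, 2L, function(col) stats::sd(col, na.rm = TRUE) == 0)
  if (any(const)) {
    warning(sum(const), " constant edge column(s) dropped before lasso")
  }
  keep <- which(!const)
  set.seed(as.integer(seed))
  cv <- glmnet::cv.glmnet(X[, keep, drop = FALSE], y, alpha = 1, nfolds = 10L)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  sel <- keep[co != 0]
  selected_regions <- if (!is.null(map) && length(sel)) {
    sort(unique(as.integer(map[sel, ])))
  } else integer(0)
  list(selected_edges = sel, selected_regions = selected_regions,
       coefficients = stats::setNames(co[co != 0], sel),
       lambda = cv$lambda.min)
}

#' Canonical-correlation region selection
#'
#' Canonical correlation between the edge block and the outcome block.
#' If the edge block is rank deficient (M >= N), it is first reduced to
#' its leading principal directions. Region scores are the absolute
#' first-canonical-vector loadings, mapped back to edges and aggregated
#' to regions by the maximum over incident edges; the top
#' round(true_signal_proportion x V) regions are flagged — the cutoff
#' uses the known simulation truth, exactly as in the benchmark
#' protocol.
#'
#' @param train_features `edge_feature_matrix`.
#' @param train_outcome Numeric vector or N x P matrix.
#' @param true_signal_proportion Fraction of regions to flag.
#' @return List with `selected_regions`, `region_scores`,
#'   `first_canonical_correlation`.
#' @export
cca_select <- function(train_features, train_outcome, true_signal_proportion) {
  stopifnot(inherits(train_features, "edge_feature_matrix"))
  X <- train_features$features
  map <- train_features$index_map
  V <- train_features$n_regions
  Y <- as.matrix(train_outcome)
  N <- nrow(X)
  if (N <= V) stop("CCA selection needs more training participants than regions")
  k_flag <- round(true_signal_proportion * V)
  ## reduce a rank-deficient edge block to principal directions
  reduce <- ncol(X) >= N
  if (reduce) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    k <- max(2L, min(N - ncol(Y) - 2L, sum(pc$sdev > 1e-10)))
    Xr <- pc$x[, seq_len(k), drop = FALSE]
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
  } else {
    Xr <- X
    rot <- NULL
  }
  cc <- stats::cancor(Xr, Y)
  xc <- cc$xcoef[, 1L]
  edge_load <- if (reduce) drop(rot %*% xc) else {
    out <- numeric(ncol(X)); out[seq_along(xc)] <- xc; out
  }
  region_scores <- vapply(seq_len(V), function(u) {
    inc <- map[, "u"] == u | map[, "v"] == u
    max(abs(edge_load[inc]))
  }, numeric(1))
  selected <- sort(order(region_scores, decreasing = TRUE)[seq_len(k_flag)])
  list(selected_regions = selected, region_scores = region_scores,
       first_canonical_correlation = cc$cor[1L])
}
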