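# Core data containers. Connectivity is stored internally in vectorized
# upper-triangle form (one row per participant, one column per unordered
# region pair u < v); the diagonal is never modeled. Missing entries are
# carried as an observation mask, never as NaN that could propagate.

#' Region-pair index table
#'
#' Enumerates the unordered region pairs (u, v), u < v, of a V-region
#' network in row-major order: (1,2), (1,3), ..., (1,V), (2,3), ...
#' This ordering defines the column layout of all vectorized edge matrices
#' in the package.
#'
#' @param n_regions Number of regions V (>= 2).
#' @return Integer matrix with M = V(V-1)/2 rows and columns `u`, `v`.
#' @export
edge_pairs <- function(n_regions) {
  V <- as.integer(n_regions)
  if (is.na(V) || V < 2L) stop("n_regions must be an integer >= 2")
  u <- rep.int(seq_len(V - 1L), times = (V - 1L):1L)
  v <- unlist(lapply(seq_len(V - 1L), function(i) (i + 1L):V), use.names = FALSE)
  cbind(u = u, v = v)
}

#' Column index of a region pair in the vectorized edge layout
#'
#' @param u,v Region indices (1-based); order does not matter.
#' @param n_regions Number of regions V.
#' @return Integer column index into the M-column edge matrix.
#' @export
pair_index <- function(u, v, n_regions) {
  V <- as.integer(n_regions)
  a <- pmin(u, v); b <- pmax(u, v)
  if (any(a < 1L) || any(b > V) || any(a == b)) {
    stop("invalid region pair for V = ", V)
  }
  as.integer((a - 1L) * V - a * (a - 1L) / 2L + (b - a))
}

## internal: vectorize one symmetric matrix to the u<v layout
.vec_upper <- function(mat, pairs) mat[cbind(pairs[, "u"], pairs[, "v"])]

#' Participant-level connectivity data
#'
#' Bundles N symmetric V x V connectivity matrices with participant
#' covariates. Edge values are stored in vectorized upper-triangle form;
#' self-edges are never read or modeled. `NA` edge values are allowed and
#' recorded in an observation mask (used e.g. for held-out participants in
#' prediction); all stored values are finite.
#'
#' @param edges One of: an N x V x V numeric array, a list of N symmetric
#'   V x V matrices, or an N x M matrix already in the `edge_pairs` column
#'   layout (M = V(V-1)/2; requires `n_regions`).
#' @param covariates Optional N x Q numeric matrix whose first column is
#'   identically 1 (the intercept). Default: intercept-only.
#' @param region_labels Optional character vector of length V.
#' @param participant_ids Optional vector of length N of unique ids.
#' @param n_regions Required when `edges` is already vectorized.
#' @return An object of class `connectivity_data` with elements `edges`
#'   (N x M), `mask` (logical N x M, TRUE = observed), `covariates`,
#'   `pairs`, `n_participants`, `n_regions`, `region_labels`,
#'   `participant_ids`.
#' @export
connectivity_data <- function(edges, covariates = NULL, region_labels = NULL,
                              participant_ids = NULL, n_regions = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) {
    V <- nrow(edges[[1L]])
    pairs <- edge_pairs(V)
    E <- t(vapply(edges, function(m) {
      .check_symmetric(m, V)
      .vec_upper(m, pairs)
    }, numeric(nrow(pairs))))
  } else if (is.array(edges) && length(dim(edges)) == 3L) {
    V <- dim(edges)[2L]
    if (dim(edges)[3L] != V) stop("edge array must be N x V x V; got dims ",
                                  paste(dim(edges), collapse = " x "))
    pairs <- edge_pairs(V)
    N <- dim(edges)[1L]
    E <- matrix(NA_real_, N, nrow(pairs))
    for (i in seq_len(N)) {
      m <- edges[i, , ]
      .check_symmetric(m, V)
      E[i, ] <- .vec_upper(m, pairs)
    }
  } else if (is.matrix(edges)) {
    if (is.null(n_regions)) stop("n_regions is required for vectorized edge input")
    V <- as.integer(n_regions)
    pairs <- edge_pairs(V)
    if (ncol(edges) != nrow(pairs)) {
      stop("vectorized edges have ", ncol(edges), " columns but V = ", V,
           " implies M = ", nrow(pairs))
    }
    E <- edges
  } else stop("unsupported edge input type")

  N <- nrow(E)
  if (any(is.infinite(E))) stop("non-finite (infinite) edge values are not allowed")
  mask <- !is.na(E)
  E[!mask] <- 0

  if (is.null(covariates)) covariates <- matrix(1, N, 1L)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != N) {
    stop("covariates have ", nrow(covariates), " rows but N = ", N, " participants")
  }
  if (any(covariates[, 1L] != 1)) stop("first covariate column must be identically 1")
  if (is.null(region_labels)) region_labels <- as.character(seq_len(V))
  if (length(region_labels) != V) stop("region_labels must have length V = ", V)
  if (is.null(participant_ids)) participant_ids <- seq_len(N)
  if (anyDuplicated(participant_ids)) stop("participant_ids must be unique")

  structure(list(
    edges = unname(E), mask = unname(mask), covariates = unname(covariates),
    pairs = pairs, n_participants = N, n_regions = V,
    region_labels = as.character(region_labels),
    participant_ids = participant_ids
  ), class = "connectivity_data")
}

.check_symmetric <- function(m, V) {
  if (!is.matrix(m) || nrow(m) != V || ncol(m) != V) {
    stop("each connectivity matrix must be ", V, " x ", V)
  }
  up <- m[upper.tri(m)]; lo <- t(m)[upper.tri(m)]
  both <- is.finite(up) & is.finite(lo)   # non-finite entries caught later
  if (any(abs(up[both] - lo[both]) > 1e-9)) {
    stop("connectivity matrix is not symmetric on stored entries")
  }
  invisible(TRUE)
}

#' Reassemble one participant's symmetric connectivity matrix
#'
#' @param data A `connectivity_data` object.
#' @param participant Participant index (1-based).
#' @return A V x V symmetric matrix; unobserved entries and the diagonal
#'   are `NA`.
#' @export
conn_matrix <- function(data, participant) {
  stopifnot(inherits(data, "connectivity_data"))
  i <- as.integer(participant)
  if (i < 1L || i > data$n_participants) stop("unknown participant index ", participant)
  V <- data$n_regions
  m <- matrix(NA_real_, V, V, dimnames = list(data$region_labels, data$region_labels))
  vals <- data$edges[i, ]
  vals[!data$mask[i, ]] <- NA_real_
  m[data$pairs] <- vals
  m[data$pairs[, c(2L, 1L)]] <- vals
  m
}

#' Participant-level behavior data
#'
#' An N x P matrix of outcome items plus participant covariates, paired
#' row-for-row with a `connectivity_data` object. `NA` outcomes are
#' recorded in an observation mask (treated as missing at random by the
#' sampler; this is also how held-out participants enter prediction).
#'
#' @param outcomes N x P numeric matrix (or vector, taken as P = 1).
#' @param covariates Optional N x Q' matrix, first column identically 1.
#' @param item_labels Optional character vector of length P.
#' @param participant_ids Optional vector of length N.
#' @return An object of class `behavior_data`.
#' @export
behavior_data <- function(outcomes, covariates = NULL, item_labels = NULL,
                          participant_ids = NULL) {
  Y <- as.matrix(outcomes)
  if (!is.numeric(Y)) stop("outcomes must be numeric")
  N <- nrow(Y); P <- ncol(Y)
  if (P < 1L) stop("need at least one behavior item (P >= 1)")
  if (any(is.infinite(Y))) stop("non-finite (infinite) outcome values are not allowed")
  mask <- !is.na(Y)
  Y[!mask] <- 0
  if (is.null(covariates)) covariates <- matrix(1, N, 1L)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != N) {
    stop("covariates have ", nrow(covariates), " rows but N = ", N, " participants")
  }
  if (any(covariates[, 1L] != 1)) stop("first covariate column must be identically 1")
  if (is.null(item_labels)) item_labels <- paste0("item", seq_len(P))
  if (length(item_labels) != P) stop("item_labels must have length P = ", P)
  if (is.null(participant_ids)) participant_ids <- seq_len(N)
  structure(list(
    outcomes = unname(Y), mask = unname(mask), covariates = unname(covariates),
    n_participants = N, n_items = P, item_labels = as.character(item_labels),
    participant_ids = participant_ids
  ), class = "behavior_data")
}

#' Prior specification for the joint model
#'
#' Defaults follow the model's reference prior: standard-normal regression
#' coefficients and intercepts, gamma(1/2, 1/2) on the error precisions,
#' and an inverse-Wishart prior on the joint latent covariance with
#' identity scale S0 and degrees of freedom m0 = V + D + 2 (D = 1 latent
#' behavior dimension), the smallest integer df giving a proper prior with
#' prior mean defined.
#'
#' @param n_regions Number of regions V (fixes the inverse-Wishart dimension).
#' @param latent_dim Behavior latent dimension D; only 1 is supported.
#' @param sigma_inv_shape,sigma_inv_rate Gamma prior on the edge precision.
#' @param tau_inv_shape,tau_inv_rate Gamma prior on the item precision.
#' @param intercept_sd Prior s.d. of participant and item intercepts.
#' @param wishart_scale Optional (V+D) x (V+D) scale matrix S0 (default identity).
#' @param wishart_df Degrees of freedom m0 (default V + D + 2).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(n_regions, latent_dim = 1L,
                       sigma_inv_shape = 0.5, sigma_inv_rate = 0.5,
                       tau_inv_shape = 0.5, tau_inv_rate = 0.5,
                       intercept_sd = 1.0,
                       wishart_scale = NULL, wishart_df = NULL) {
  V <- as.integer(n_regions)
  D <- as.integer(latent_dim)
  if (D != 1L) stop("only latent_dim = 1 is supported")
  K <- V + D
  if (is.null(wishart_scale)) wishart_scale <- diag(K)
  wishart_scale <- as.matrix(wishart_scale)
  if (!all(dim(wishart_scale) == K)) stop("wishart_scale must be ", K, " x ", K)
  if (is.null(wishart_df)) wishart_df <- K + 2
  if (wishart_df < K) stop("wishart_df must be >= V + D for a proper prior")
  vals <- c(sigma_inv_shape, sigma_inv_rate, tau_inv_shape, tau_inv_rate, intercept_sd)
  if (any(vals <= 0)) stop("variance hyperparameters must be strictly positive")
  structure(list(
    sigma_inv_shape = sigma_inv_shape, sigma_inv_rate = sigma_inv_rate,
    tau_inv_shape = tau_inv_shape, tau_inv_rate = tau_inv_rate,
    intercept_sd = intercept_sd,
    wishart_scale = wishart_scale, wishart_df = wishart_df,
    n_regions = V, latent_dim = D
  ), class = "prior_spec")
}

#' Standardize edge values across participants
#'
#' Centers and scales each region pair's edge values to mean 0 and unit
#' variance across participants (sample s.d., n - 1 denominator),
#' computed over observed entries. With edge-wise standardization the
#' node-level means are zero, so additive node effects are unnecessary in
#' the model.
#'
#' @param data A `connectivity_data` object with N >= 2.
#' @return A `connectivity_data` object with standardized edges.
#' @export
standardize_edges <- function(data) {
  stopifnot(inherits(data, "connectivity_data"))
  if (data$n_participants < 2L) stop("standardization needs N >= 2 participants")
  E <- data$edges
  E[!data$mask] <- NA_real_
  mu <- colMeans(E, na.rm = TRUE)
  sd_ <- apply(E, 2L, stats::sd, na.rm = TRUE)
  bad <- which(!is.finite(sd_) | sd_ == 0)
  if (length(bad)) {
    pr <- data$pairs[bad, , drop = FALSE]
    stop("zero-variance edges cannot be standardized: ",
         paste(sprintf("(%d,%d)", pr[, "u"], pr[, "v"]), collapse = ", "))
  }
  E <- sweep(sweep(E, 2L, mu, "-"), 2L, sd_, "/")
  E[!data$mask] <- 0
  out <- data
  out$edges <- E
  out
}

#' @export
print.connectivity_data <- function(x, ...) {
  cat("connectivity_data: N =", x$n_participants, "participants, V =",
      x$n_regions, "regions,", ncol(x$covariates), "covariate column(s)\n")
  miss <- sum(!x$mask)
  if (miss > 0) cat("  missing edge entries:", miss, "\n")
  invisible(x)
}

#' @export
print.behavior_data <- function(x, ...) {
  cat("behavior_data: N =", x$n_participants, "participants, P =",
      x$n_items, "item(s),", ncol(x$covariates), "covariate column(s)\n")
  invisible(x)
}
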