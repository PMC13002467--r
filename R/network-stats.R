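# Weighted-graph topology statistics on latent-network reconstructions.
# Edge weights can be negative (they are covariance-like); path-based
# centralities first shift all weights up by the magnitude of the most
# negative edge, drop edges that land exactly at zero, and use the
# reciprocal weight as the path distance.

#' Weighted graph container
#'
#' @param weights Symmetric V x V numeric matrix; the diagonal is forced
#'   to zero.
#' @param labels Optional node labels.
#' @return An object of class `weighted_graph`.
#' @export
weighted_graph <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  V <- nrow(weights)
  if (ncol(weights) != V) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-9) stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(labels)) labels <- as.character(seq_len(V))
  if (length(labels) != V) stop("labels must have length ", V)
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = as.character(labels)),
            class = "weighted_graph")
}

#' Latent-network reconstruction from fitted latent positions
#'
#' The rank-one network implied by the posterior-mean latent positions:
#' weights are the outer product z z' of one participant's latent vector
#' (or of the participant-averaged vector for `participant = "average"`),
#' with a zero diagonal. A global sign flip of z leaves the graph
#' unchanged.
#'
#' @param Z_mean N x V matrix of posterior-mean latent positions (e.g.
#'   `samples$latent_mean_Z`).
#' @param participant Participant index, or `"average"`.
#' @param labels Optional region labels.
#' @return A `weighted_graph`.
#' @export
latent_network <- function(Z_mean, participant = "average", labels = NULL) {
  Z_mean <- as.matrix(Z_mean)
  if (identical(participant, "average")) {
    z <- colMeans(Z_mean)
  } else {
    i <- as.integer(participant)
    if (is.na(i) || i < 1L || i > nrow(Z_mean)) {
      stop("unknown participant: ", participant)
    }
    z <- Z_mean[i, ]
  }
  weighted_graph(tcrossprod(z), labels)
}

#' Node strength
#'
#' The weighted-network extension of degree: the sum of edge weights
#' incident to each node (diagonal excluded).
#'
#' @param g A `weighted_graph`.
#' @return Named length-V numeric vector.
#' @export
node_strength <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  rowSums(g$weights)
}

## internal: shift weights so all are positive; zero edges are dropped
.positive_weights <- function(W) {
  mn <- min(W[upper.tri(W)])
  if (mn < 0) {
    W <- W + abs(mn)
    diag(W) <- 0
  }
  W
}

## internal: igraph from a positive-weight matrix, zero edges absent
.as_igraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Closeness centrality with the negative-edge shift
#'
#' If any edge weight is negative, a uniform magnitude equal to the most
#' negative edge is added to all edges so all weights are positive; edges
#' shifted exactly to zero are treated as absent. Path distances are the
#' reciprocal weights, and closeness for a node is the reciprocal of the
#' sum of shortest-path distances to the nodes it can reach; nodes that
#' can reach nothing get closeness 0 and are flagged.
#'
#' @param g A `weighted_graph` with V >= 2.
#' @return Named length-V numeric vector with attribute `disconnected`
#'   (logical vector flagging isolated nodes).
#' @export
shifted_closeness <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  V <- nrow(g$weights)
  if (V < 2L) stop("closeness needs at least 2 nodes")
  W <- .positive_weights(g$weights)
  ig <- .as_igraph(W)
  D <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  cl <- numeric(V)
  disc <- logical(V)
  for (u in seq_len(V)) {
    d <- D[u, -u]
    reach <- is.finite(d)
    if (!any(reach)) {
      cl[u] <- 0
      disc[u] <- TRUE
    } else {
      cl[u] <- 1 / sum(d[reach])
    }
  }
  names(cl) <- g$labels
  attr(cl, "disconnected") <- disc
  cl
}

#' Betweenness centrality with the negative-edge shift
#'
#' Weighted shortest-path betweenness (Brandes counting, ties split
#' fractionally) on the positively shifted graph, with path distance
#' equal to the reciprocal edge weight.
#'
#' @param g A `weighted_graph` with V >= 2.
#' @return Named length-V numeric vector.
#' @export
betweenness <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (nrow(g$weights) < 2L) stop("betweenness needs at least 2 nodes")
  W <- .positive_weights(g$weights)
  ig <- .as_igraph(W)
  bt <- igraph::betweenness(ig, weights = 1 / igraph::E(ig)$weight,
                            directed = FALSE)
  stats::setNames(as.numeric(bt), g$labels)
}

#' Sample skewness and excess kurtosis
#'
#' Plain moment-based shape summaries: the standardized third sample
#' moment and the standardized fourth sample moment minus 3, both with
#' the biased (1/n) moment estimators.
#'
#' @param values Numeric vector of length >= 4.
#' @return Named vector `c(skewness = , excess_kurtosis = )`; `NA` for
#'   zero-variance input.
#' @export
moment_summary <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 finite values")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(c(skewness = NA_real_, excess_kurtosis = NA_real_))
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  c(skewness = m3 / s2^1.5, excess_kurtosis = m4 / s2^2 - 3)
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("weighted_graph:", nrow(x$weights), "nodes,",
      sum(x$weights[upper.tri(x$weights)] != 0), "nonzero edges\n")
  invisible(x)
}
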