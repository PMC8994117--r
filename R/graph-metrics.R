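#' @include AllClasses.R
NULL

.weightMatrix <- function(net) {
  w <- if (is(net, "ConnectivityMatrix")) edgeWeights(net) else as.matrix(net)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (max(abs(w - t(w))) > 1e-12) stop("weight matrix must be symmetric")
  diag(w) <- 0
  if (any(w < 0)) stop("edge weights must be positive (threshold the network first)")
  w
}

#' Total functional-connectivity strength
#'
#' Sum of the weights of all suprathreshold connections, each undirected
#' edge counted once.
#'
#' @param net a thresholded [ConnectivityMatrix-class] or a symmetric
#'   non-negative weight matrix (0 = absent edge).
#' @return Non-negative scalar; 0 for an empty network.
#' @export
fcStrength <- function(net) {
  w <- .weightMatrix(net)
  sum(w[upper.tri(w)])
}

## all-pairs weighted shortest-path distances with edge length = 1/weight
.spDistances <- function(w) {
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

.globalEfficiencyW <- function(w) {
  n <- nrow(w)
  if (n < 2L || all(w == 0)) return(0)
  d <- .spDistances(w)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0   # disconnected pairs contribute 0
  mean(inv)
}

#' Global network efficiency
#'
#' Mean over all unordered node pairs of the inverse weighted shortest-path
#' length, with edge length defined as the inverse of the edge weight (the
#' standard weighted-efficiency convention). Disconnected pairs contribute
#' 0; an empty or single-node network has efficiency 0.
#'
#' @inheritParams fcStrength
#' @return Non-negative scalar.
#' @examples
#' w <- matrix(c(0, 0.5, 0.5, 0), 2, 2)  # single edge of weight 0.5
#' globalEfficiency(w)                   # = 0.5
#' @export
globalEfficiency <- function(net) .globalEfficiencyW(.weightMatrix(net))

#' Local network efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbourhood
#' subgraph: the subgraph induced by the node's neighbours, excluding the
#' node itself and keeping the original weights between neighbours. Nodes
#' with fewer than two neighbours contribute 0.
#'
#' @inheritParams fcStrength
#' @return Non-negative scalar.
#' @export
localEfficiency <- function(net) {
  w <- .weightMatrix(net)
  n <- nrow(w)
  if (n == 0L) return(0)
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) return(0)
    .globalEfficiencyW(w[nb, nb, drop = FALSE])
  }, 1.0)
  mean(eff)
}

#' All three global network properties of one network
#'
#' @inheritParams fcStrength
#' @return A [GlobalNetworkProperties-class] object.
#' @export
globalNetworkProperties <- function(net) {
  w <- .weightMatrix(net)
  new("GlobalNetworkProperties",
      fcStrength = sum(w[upper.tri(w)]),
      globalEfficiency = .globalEfficiencyW(w),
      localEfficiency = localEfficiency(w),
      nNodes = nrow(w),
      nEdges = sum(w[upper.tri(w)] != 0))
}

#' Control-referenced Z-score of a network property
#'
#' `Z = (P - mu) / delta`, where `P` is the patient value and `mu`, `delta`
#' are the mean and standard deviation (denominator n - 1) of the control
#' values.
#'
#' @param value patient value(s).
#' @param controlValues numeric vector of at least two control values with
#'   non-zero standard deviation.
#' @return Z-score(s).
#' @examples
#' networkZscore(12, c(8, 10, 12))  # = 1
#' @export
networkZscore <- function(value, controlValues) {
  if (length(controlValues) < 2L)
    stop("at least two control values are required")
  s <- stats::sd(controlValues)
  if (!is.finite(s) || s == 0)
    stop("control values have zero standard deviation")
  (value - mean(controlValues)) / s
}
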