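#' Weighted clustering coefficient of one node
#'
#' For a weighted graph with symmetric weights `w` in `[0, 1]` and zero
#' diagonal, the clustering coefficient of vertex i is the ratio of the
#' total weight of closed triples through i to the total weight of open
#' neighbor pairs:
#' `C_i = sum_{k != i} sum_{l != i, l != k} w_ik w_il w_kl /
#'        sum_{k != i} sum_{l != i, l != k} w_ik w_il`.
#' A node with fewer than two weighted neighbors (zero denominator)
#' returns 0.
#'
#' @param w symmetric numeric weight matrix (entries in `[0, 1]`, zero
#'   diagonal), e.g. a `pli_matrix`; treated as a fully weighted graph,
#'   no thresholding.
#' @param i node index or label.
#' @return Scalar in `[0, 1]`.
#' @export
node_clustering <- function(w, i) {
  check_weight_matrix(w, min_n = 3)
  if (is.character(i)) i <- match(i, rownames(w))
  wi <- w[i, ]
  num <- drop(wi %*% w %*% wi)          # sum_{k,l} w_ik w_kl w_li
  den <- sum(wi)^2 - sum(wi^2)          # sum_{k != l} w_ik w_il
  if (den == 0) 0 else num / den
}

#' Mean weighted clustering coefficient
#'
#' Arithmetic mean of [node_clustering()] over all nodes: the network's
#' local-segregation summary.
#'
#' @inheritParams node_clustering
#' @return Scalar in `[0, 1]`.
#' @export
mean_clustering <- function(w) {
  check_weight_matrix(w, min_n = 3)
  mean(vapply(seq_len(nrow(w)), function(i) node_clustering(w, i),
              numeric(1)))
}

#' All-pairs shortest path lengths over inverse weights
#'
#' The length of an edge is the inverse of its weight (`1/w`, infinite for
#' zero weight); the distance between two nodes is the length of the
#' shortest (possibly multi-hop) path, computed with Dijkstra's algorithm.
#'
#' @inheritParams node_clustering
#' @return Symmetric matrix of path lengths with zero diagonal;
#'   `Inf` for unreachable pairs.
#' @export
shortest_path_lengths <- function(w) {
  check_weight_matrix(w, min_n = 2)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  if (!is.null(rownames(w))) dimnames(d) <- dimnames(w)
  d
}

#' Characteristic path length (harmonic aggregation)
#'
#' Aggregates all-pairs shortest path lengths as the inverse of the mean
#' inverse path length over ordered pairs,
#' `L = 1 / ( (1/(N(N-1))) * sum_{i} sum_{j != i} 1/L_ij )`
#' (the efficiency-based form of Latora and Marchiori). Unreachable pairs
#' contribute `1/L_ij = 0`; a fully disconnected graph yields `Inf`
#' (flagged by a warning, not an error).
#'
#' @inheritParams node_clustering
#' @return Positive scalar, or `Inf` for a fully disconnected graph.
#' @export
characteristic_path_length <- function(w) {
  check_weight_matrix(w, min_n = 2)
  d <- shortest_path_lengths(w)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  eff <- mean(inv)
  if (eff == 0) {
    warning("graph is fully disconnected; characteristic path length is Inf",
            call. = FALSE)
    return(Inf)
  }
  1 / eff
}

#' Graph metrics for one connectivity matrix
#'
#' Convenience wrapper returning the mean clustering coefficient and the
#' characteristic path length of a PLI-weighted network.
#'
#' @inheritParams node_clustering
#' @return Named list with elements `C` and `L`.
#' @export
graph_metrics <- function(w) {
  list(C = mean_clustering(w), L = characteristic_path_length(w))
}

check_weight_matrix <- function(w, min_n = 2) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop("weight matrix must be square", call. = FALSE)
  }
  if (nrow(w) < min_n) {
    stop("need at least ", min_n, " nodes", call. = FALSE)
  }
  if (max(abs(w - t(w))) > 1e-12) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(w) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  invisible(w)
}
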