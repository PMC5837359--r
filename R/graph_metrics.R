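# Nodal graph metrics. Weighted degree, participation coefficient and nodal
# strength are analysed raw; clustering, betweenness, closeness, local
# efficiency and eigenvector centrality operate on the binarized graph and are
# normalized against degree-preserving random graphs (see normalize_metric).

#' Weighted degree
#'
#' Sum of retained edge weights at each node of a thresholded graph.
#'
#' @param g a `thresholded_graph` (or weighted adjacency matrix)
#' @return per-node numeric vector
#' @export
weighted_degree <- function(g) {
  rowSums(as_weighted_adjacency(g))
}

#' Nodal connectivity strength
#'
#' Row sums of the unthresholded association matrix: the strength of every
#' connection a node makes, regardless of thresholding.
#'
#' @param assoc association matrix
#' @return per-node numeric vector
#' @export
nodal_strength <- function(assoc) {
  check_square_symmetric(assoc, what = "association matrix")
  rowSums(assoc)
}

#' Louvain community detection
#'
#' Greedy modularity maximization on the retained z weights. Negative retained
#' weights (possible only on backbone edges of anticorrelated node pairs) are
#' clipped to 0 for the community search. Deterministic given `seed`.
#'
#' @param g a `thresholded_graph` (or weighted adjacency matrix)
#' @param seed integer seed
#' @return list with `membership` (0-based integer vector) and `modularity`
#' @export
louvain_partition <- function(g, seed = 1) {
  w <- as_weighted_adjacency(g)
  w[w < 0] <- 0
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  cl <- with_seed(seed, igraph::cluster_louvain(ig))
  list(
    membership = as.integer(igraph::membership(cl)) - 1L,
    modularity = max(igraph::modularity(cl))
  )
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (kappa_is / k_i)^2`, where `kappa_is` is the summed weight
#' from node i into community s and `k_i` its weighted degree. Nodes with zero
#' degree receive 0. Computed on weights; communities from
#' [louvain_partition()] (or any partition covering all nodes).
#'
#' @param g a `thresholded_graph` (or weighted adjacency matrix)
#' @param partition list with `membership`, or an integer membership vector
#' @return per-node numeric vector in \[0, 1\]
#' @export
participation_coefficient <- function(g, partition) {
  w <- as_weighted_adjacency(g)
  membership <- if (is.list(partition)) partition$membership else partition
  if (length(membership) != nrow(w)) stop_arg("partition must cover all nodes")
  k <- rowSums(w)
  comm <- sort(unique(membership))
  ind <- outer(membership, comm, "==") * 1
  kappa <- w %*% ind
  p <- rep(0, nrow(w))
  nz <- k > 0
  p[nz] <- 1 - rowSums((kappa[nz, , drop = FALSE] / k[nz])^2)
  p
}

#' Binary clustering coefficient
#'
#' Fraction of a node's neighbour pairs that are themselves connected;
#' 0 for nodes with degree < 2.
#'
#' @param g binary adjacency matrix or `thresholded_graph`
#' @return per-node numeric vector in \[0, 1\]
#' @export
clustering_coefficient <- function(g) {
  b <- as_binary_adjacency(g)
  cc <- igraph::transitivity(binary_igraph(b), type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  cc
}

geodesic_distances <- function(b, require_connected = TRUE) {
  d <- igraph::distances(binary_igraph(b))
  if (require_connected && any(is.infinite(d))) {
    stop_arg("graph must be connected")
  }
  d
}

#' Betweenness centrality (normalized)
#'
#' Fraction of unweighted shortest paths between other node pairs passing
#' through each node, normalized by `(N-1)(N-2)/2`.
#'
#' @param g binary adjacency matrix or `thresholded_graph`
#' @return per-node numeric vector in \[0, 1\]
#' @export
betweenness_centrality <- function(g) {
  b <- as_binary_adjacency(g)
  n <- nrow(b)
  geodesic_distances(b)  # connectivity check
  raw <- igraph::betweenness(binary_igraph(b), directed = FALSE)
  if (n <= 2) return(rep(0, n))
  as.numeric(raw) / ((n - 1) * (n - 2) / 2)
}

#' Closeness centrality
#'
#' `(N - 1) / sum_j d(i, j)` over unweighted geodesic distances.
#'
#' @param g binary adjacency matrix or `thresholded_graph`
#' @return per-node numeric vector in (0, 1\]
#' @export
closeness_centrality <- function(g) {
  b <- as_binary_adjacency(g)
  d <- geodesic_distances(b)
  (nrow(b) - 1) / rowSums(d)
}

#' Global efficiency
#'
#' Mean inverse geodesic distance over ordered node pairs.
#'
#' @param g binary adjacency matrix or `thresholded_graph`
#' @return scalar in (0, 1\]
#' @export
global_efficiency <- function(g) {
  b <- as_binary_adjacency(g)
  d <- geodesic_distances(b)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (nrow(b) * (nrow(b) - 1))
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by each node's neighbours
#' (excluding the node itself); 0 for degree < 2; neighbour pairs disconnected
#' within the subgraph contribute 0.
#'
#' @param g binary adjacency matrix or `thresholded_graph`
#' @return per-node numeric vector in \[0, 1\]
#' @export
local_efficiency <- function(g) {
  b <- as_binary_adjacency(g)
  n <- nrow(b)
  vapply(seq_len(n), function(i) {
    nb <- which(b[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    d <- igraph::distances(binary_igraph(b[nb, nb, drop = FALSE]))
    inv <- 1 / d
    inv[is.infinite(d)] <- 0
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the binary adjacency by power iteration (run on
#' `A + I`, which shares eigenvectors with `A` and guarantees convergence on
#' bipartite graphs), returned with non-negative entries and unit L2 norm.
#'
#' @param g binary adjacency matrix or `thresholded_graph`
#' @param tol sup-norm convergence tolerance
#' @param max_iter iteration cap; non-convergence raises an error reporting
#'   the residual
#' @return per-node numeric vector, unit L2 norm
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 10000) {
  b <- as_binary_adjacency(g)
  geodesic_distances(b)  # connectivity check
  n <- nrow(b)
  a <- b + diag(n)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(a %*% x)
    y <- y / sqrt(sum(y^2))
    residual <- max(abs(y - x))
    x <- y
    if (residual < tol) return(x)
  }
  stop_arg("eigenvector centrality did not converge after ", max_iter,
           " iterations (residual ", signif(residual, 3), ")")
}

#' Degree-preserving, connectivity-preserving randomization
#'
#' Randomizes a connected binary graph by attempted double-edge swaps
#' (`swap_factor * E` attempts), rejecting any swap that would create a
#' self-loop or multi-edge or disconnect the graph. The degree sequence is
#' preserved exactly.
#'
#' @param g binary adjacency matrix or `thresholded_graph`
#' @param swap_factor attempted swaps per edge
#' @param seed integer seed (NULL uses the current RNG state)
#' @return randomized binary adjacency matrix
#' @export
degree_preserving_randomize <- function(g, swap_factor = 10, seed = NULL) {
  b <- as_binary_adjacency(g)
  geodesic_distances(b)  # connectivity check
  idx <- which(upper.tri(b) & b == 1, arr.ind = TRUE)
  run <- function() .rewire_degseq_cpp(idx - 1L, nrow(b),
                                       as.integer(swap_factor * nrow(idx)))
  edges <- if (is.null(seed)) run() else with_seed(seed, run())
  out <- matrix(0, nrow(b), ncol(b))
  out[edges + 1L] <- 1
  out <- out + t(out)
  out[out > 1] <- 1
  out
}

#' Ensemble of degree-matched random graphs
#'
#' @param g binary adjacency matrix or `thresholded_graph`
#' @param n_random ensemble size
#' @param swap_factor attempted swaps per edge, per member
#' @param seed integer seed
#' @return list with `graphs` (list of adjacency matrices), `swap_factor`,
#'   `seed`
#' @export
random_ensemble <- function(g, n_random = 100, swap_factor = 10, seed = 1) {
  b <- as_binary_adjacency(g)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_random))
  graphs <- lapply(seeds, function(s) {
    degree_preserving_randomize(b, swap_factor = swap_factor, seed = s)
  })
  list(graphs = graphs, swap_factor = swap_factor, seed = seed)
}

binary_metric_funs <- function() {
  list(
    clustering = clustering_coefficient,
    betweenness = betweenness_centrality,
    closeness = closeness_centrality,
    local_efficiency = local_efficiency,
    eigenvector = eigenvector_centrality
  )
}

#' Null-model normalization of a binary metric
#'
#' Divides the observed per-node metric by its mean over a degree-matched
#' random-graph ensemble. Nodes whose ensemble mean is 0 get a normalized
#' value of 0 and are flagged in the `zero_mean_nodes` attribute. Only the
#' binarized metrics are normalized; weighted degree, participation
#' coefficient and nodal strength are analysed raw.
#'
#' @param observed per-node metric values on the real graph
#' @param ensemble ensemble from [random_ensemble()]
#' @param metric one of `"clustering"`, `"betweenness"`, `"closeness"`,
#'   `"local_efficiency"`, `"eigenvector"`
#' @return per-node normalized values (attribute `zero_mean_nodes` lists
#'   1-based indices where the ensemble mean was 0)
#' @export
normalize_metric <- function(observed, ensemble, metric) {
  funs <- binary_metric_funs()
  if (!metric %in% names(funs)) {
    stop_arg("metric must be one of: ", paste(names(funs), collapse = ", "))
  }
  if (!is.list(ensemble$graphs) || length(ensemble$graphs) == 0) {
    stop_arg("ensemble must contain at least one graph")
  }
  f <- funs[[metric]]
  vals <- vapply(ensemble$graphs, f, numeric(length(observed)))
  null_mean <- rowMeans(vals)
  out <- ifelse(null_mean == 0, 0, observed / null_mean)
  attr(out, "zero_mean_nodes") <- which(null_mean == 0)
  out
}

#' All nodal metrics for one thresholded graph
#'
#' Convenience wrapper computing the raw metrics (weighted degree,
#' participation coefficient) and, when `n_random > 0`, the null-normalized
#' binarized metrics.
#'
#' @param g a `thresholded_graph`
#' @param seed seed for Louvain and the random ensemble
#' @param n_random ensemble size for normalization (0 skips normalization)
#' @param swap_factor attempted swaps per edge in the null model
#' @return named list of per-node metric vectors; normalized entries are
#'   suffixed `_norm`
#' @export
metric_panel <- function(g, seed = 1, n_random = 0, swap_factor = 10) {
  partition <- louvain_partition(g, seed = seed)
  out <- list(
    weighted_degree = weighted_degree(g),
    participation = participation_coefficient(g, partition)
  )
  funs <- binary_metric_funs()
  raw <- lapply(funs, function(f) f(g$binary))
  out <- c(out, raw)
  if (n_random > 0) {
    ens <- random_ensemble(g$binary, n_random = n_random,
                           swap_factor = swap_factor, seed = seed)
    norm <- lapply(names(funs), function(nm) {
      normalize_metric(raw[[nm]], ens, nm)
    })
    names(norm) <- paste0(names(funs), "_norm")
    out <- c(out, norm)
  }
  out
}
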