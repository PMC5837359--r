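#' Fisher-z association matrix from node time series
#'
#' Computes all pairwise Pearson correlations between node time series and
#' Fisher-z transforms them (`atanh`). Correlations are clipped to
#' `|r| <= 1 - 1e-12` before the transform so collinear nodes map to a large
#' finite z rather than infinity. The diagonal is set to 0.
#'
#' @param timeseries node x time numeric matrix (>= 3 time points)
#' @return symmetric node x node matrix of Fisher-z values, zero diagonal
#' @export
compute_association_matrix <- function(timeseries) {
  if (!is.matrix(timeseries) || !is.numeric(timeseries)) {
    stop_arg("timeseries must be a numeric matrix (nodes x time)")
  }
  if (ncol(timeseries) < 3) stop_arg("at least 3 time points are required")
  vars <- apply(timeseries, 1, stats::var)
  if (any(vars == 0)) {
    stop_arg("zero-variance node(s): ",
             paste(which(vars == 0) - 1L, collapse = ", "))
  }
  r <- stats::cor(t(timeseries))
  cap <- 1 - 1e-12
  r[r > cap] <- cap
  r[r < -cap] <- -cap
  z <- atanh(r)
  diag(z) <- 0
  (z + t(z)) / 2
}

#' Element-wise mean of association matrices
#'
#' @param matrices non-empty list of equally sized association matrices
#' @return the group-averaged association matrix
#' @export
group_average_matrix <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0) {
    stop_arg("matrices must be a non-empty list")
  }
  dims <- vapply(matrices, function(m) dim(m), integer(2))
  if (any(dims != dims[1, 1])) stop_arg("all matrices must share dimensions")
  Reduce(`+`, matrices) / length(matrices)
}

#' Pairwise difference of association matrices
#'
#' @param a,b association matrices of equal dimension
#' @return `a - b`
#' @export
matrix_difference <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop_arg("matrices must share dimensions")
  a - b
}

#' Proportional thresholding with a spanning-tree backbone
#'
#' Thresholds an association matrix at a target edge density while
#' guaranteeing a connected graph. The maximum-weight spanning tree of the z
#' matrix (Kruskal on descending z, ties broken by lexicographic node-pair
#' order) is retained unconditionally as the backbone; remaining edges are
#' added in descending z order until the graph holds
#' `max(N - 1, round(density * N * (N - 1) / 2))` edges, with round-half-away
#' rounding. By default edges are ranked by signed z, so only the strongest
#' positive correlations enter; set `rank_by = "absolute"` to rank by `|z|`.
#'
#' @param assoc symmetric association matrix with finite entries
#' @param density target edge density in (0, 1]
#' @param rank_by `"signed"` (default) or `"absolute"` edge ranking
#' @return a `thresholded_graph`: list with `density`, `weighted_adjacency`
#'   (retained z values), `binary_adjacency`, `backbone_edges` (m x 2,
#'   1-based), `n_edges`
#' @export
threshold_graph <- function(assoc, density, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  check_square_symmetric(assoc, what = "association matrix")
  n <- nrow(assoc)
  if (n < 2) stop_arg("at least 2 nodes are required")
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1) {
    stop_arg("density must lie in (0, 1]")
  }

  idx <- which(upper.tri(assoc), arr.ind = TRUE)
  z <- assoc[idx]
  key <- if (rank_by == "signed") z else abs(z)
  ord <- order(-key, idx[, 1], idx[, 2])

  # Kruskal on the ranked edge list: first spanning set = max-weight tree
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  in_tree <- logical(length(ord))
  tree_count <- 0L
  for (k in seq_along(ord)) {
    e <- ord[k]
    ra <- find(idx[e, 1])
    rb <- find(idx[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      in_tree[k] <- TRUE
      tree_count <- tree_count + 1L
      if (tree_count == n - 1L) break
    }
  }
  if (tree_count < n - 1L) stop_arg("internal error: spanning tree incomplete")

  e_target <- max(n - 1, round_half_away(density * n * (n - 1) / 2))
  selected <- logical(length(ord))
  selected[in_tree] <- TRUE
  count <- tree_count
  for (k in seq_along(ord)) {
    if (count >= e_target) break
    if (!selected[k]) {
      selected[k] <- TRUE
      count <- count + 1L
    }
  }

  keep <- ord[selected]
  binary <- matrix(0, n, n)
  weighted <- matrix(0, n, n)
  binary[idx[keep, , drop = FALSE]] <- 1
  weighted[idx[keep, , drop = FALSE]] <- assoc[idx[keep, , drop = FALSE]]
  binary <- binary + t(binary)
  weighted <- weighted + t(weighted)

  structure(
    list(
      density = density,
      weighted = weighted,
      binary = binary,
      backbone_edges = idx[ord[in_tree], , drop = FALSE],
      n_edges = as.integer(count)
    ),
    class = "thresholded_graph"
  )
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat("Thresholded graph:", nrow(x$binary), "nodes,", x$n_edges,
      "edges at density", x$density, "\n")
  invisible(x)
}
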