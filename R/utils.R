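# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# round() uses banker's rounding; edge budgets need round-half-away-from-zero.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_arg <- function(...) {
  stop(..., call. = FALSE)
}

check_square_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) stop_arg(what, " must be a numeric matrix")
  if (nrow(m) != ncol(m)) stop_arg(what, " must be square")
  if (any(!is.finite(m))) stop_arg(what, " contains non-finite entries")
  if (max(abs(m - t(m))) > tol) stop_arg(what, " must be symmetric (tolerance ", tol, ")")
  invisible(m)
}

is_binary_adjacency <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1)) && all(diag(m) == 0)
}

# Accept either a thresholded_graph or a plain binary adjacency matrix.
as_binary_adjacency <- function(g) {
  if (inherits(g, "thresholded_graph")) {
    return(g$binary)
  }
  check_square_symmetric(g, what = "adjacency")
  if (!is_binary_adjacency(g)) stop_arg("adjacency must be 0/1 with zero diagonal")
  g
}

as_weighted_adjacency <- function(g) {
  if (inherits(g, "thresholded_graph")) {
    return(g$weighted)
  }
  check_square_symmetric(g, what = "adjacency")
  g
}

binary_igraph <- function(b) {
  igraph::graph_from_adjacency_matrix(b, mode = "undirected", diag = FALSE)
}
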