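# Independent brute-force implementations of every nodal metric, used as
# oracles. These deliberately share no code with the package internals: plain
# loops, Floyd-Warshall distances, dense eigendecomposition.

random_connected_graph <- function(n, p = 0.4) {
  repeat {
    b <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p) b[i, j] <- b[j, i] <- 1
      }
    }
    if (oracle_is_connected(b)) return(b)
  }
}

oracle_is_connected <- function(b) {
  n <- nrow(b)
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  frontier <- 1
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in which(b[v, ] == 1)) {
        if (!seen[u]) {
          seen[u] <- TRUE
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  all(seen)
}

oracle_distances <- function(b) {
  n <- nrow(b)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[b == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# number of geodesics between every ordered pair, by dynamic programming in
# order of increasing distance
oracle_path_counts <- function(b, d) {
  n <- nrow(b)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (dist in sort(unique(d[s, is.finite(d[s, ]) & d[s, ] > 0]))) {
      for (t in which(d[s, ] == dist)) {
        preds <- which(b[, t] == 1 & d[s, ] == dist - 1)
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  sigma
}

oracle_weighted_degree <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) out[i] <- out[i] + w[i, j]
  }
  out
}

oracle_clustering <- function(b) {
  n <- nrow(b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(b[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in nb) for (c in nb) if (a < c && b[a, c] == 1) tri <- tri + 1
    out[i] <- 2 * tri / (k * (k - 1))
  }
  out
}

oracle_betweenness <- function(b) {
  n <- nrow(b)
  d <- oracle_distances(b)
  sigma <- oracle_path_counts(b, d)
  out <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    out[v] <- acc
  }
  if (n <= 2) return(rep(0, n))
  out / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(b) {
  d <- oracle_distances(b)
  (nrow(b) - 1) / rowSums(d)
}

oracle_global_efficiency <- function(b) {
  d <- oracle_distances(b)
  n <- nrow(b)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) acc <- acc + 1 / d[i, j]
  }
  acc / (n * (n - 1))
}

oracle_local_efficiency <- function(b) {
  n <- nrow(b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(b[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    sub <- b[nb, nb, drop = FALSE]
    d <- oracle_distances(sub)
    acc <- 0
    for (a in seq_len(k)) for (c in seq_len(k)) {
      if (a != c && is.finite(d[a, c])) acc <- acc + 1 / d[a, c]
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

oracle_eigenvector <- function(b) {
  e <- eigen(b, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  v
}

oracle_participation <- function(w, membership) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ])
    if (k == 0) next
    acc <- 0
    for (s in unique(membership)) {
      kis <- sum(w[i, membership == s])
      acc <- acc + (kis / k)^2
    }
    out[i] <- 1 - acc
  }
  out
}

# two-community membership agreement up to label permutation
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

small_cohort_config <- function(...) {
  cohort_config(
    n_cortical = 40, n_communities = 4, n_subcortical = 8, n_cerebellar = 6,
    group_sizes = c(AD = 4, PSP = 4, CTRL = 4), t_points = 60, ...
  )
}

ar1_corr <- function(p, rho = 0.3) {
  outer(seq_len(p), seq_len(p), function(i, j) rho^abs(i - j))
}

sample_corr <- function(n, pop_chol) {
  x <- matrix(rnorm(n * ncol(pop_chol)), n) %*% pop_chol
  cor(x)
}
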