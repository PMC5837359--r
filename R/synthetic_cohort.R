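#' Planted base connectivity network
#'
#' Draws a symmetric, zero-diagonal weight matrix with stochastic-block
#' community structure and a designated hub set. Each node pair receives an
#' edge with probability `p_in` (same community) or `p_out` (different
#' communities); present edges get a weight drawn uniformly on \[0.5, 1\].
#' A fraction `hub_fraction` of cortical nodes, spread round-robin across the
#' cortical communities, is designated as hubs; all weights incident to a hub
#' are multiplied by `hub_boost` (an edge between two hubs is boosted twice).
#' Edges internal to the cerebellum are multiplied by `cerebellar_boost`,
#' emulating the strong intra-cerebellar coherence characteristic of
#' resting-state data; the cerebellar block thereby carries the largest row
#' sums, and, because the cerebellum is the tau-free PET reference region,
#' those rows are stable under burden modulation.
#'
#' @param node_table node metadata from [make_node_table()]
#' @param p_in within-community edge probability
#' @param p_out between-community edge probability (`p_out <= p_in`)
#' @param hub_fraction fraction of cortical nodes designated hubs
#' @param hub_boost multiplier (>= 1) applied to hub-incident weights
#' @param cerebellar_boost multiplier (>= 1) applied to weights internal to
#'   the cerebellum
#' @param seed integer seed
#' @return symmetric numeric matrix with attribute `hubs` (0-based node ids)
#' @export
make_base_network <- function(node_table, p_in = 0.25, p_out = 0.02,
                              hub_fraction = 0.1, hub_boost = 1.2,
                              cerebellar_boost = 1, seed = 1) {
  validate_node_table(node_table)
  if (p_out > p_in) stop_arg("p_out must not exceed p_in")
  if (p_in < 0 || p_in > 1 || p_out < 0) stop_arg("probabilities must lie in [0, 1]")
  if (hub_boost < 1) stop_arg("hub_boost must be >= 1")
  if (cerebellar_boost < 1) stop_arg("cerebellar_boost must be >= 1")
  if (hub_fraction < 0 || hub_fraction > 1) stop_arg("hub_fraction must lie in [0, 1]")

  n <- nrow(node_table)
  comm <- node_table$community
  w <- with_seed(seed, {
    same <- outer(comm, comm, "==")
    p <- ifelse(same, p_in, p_out)
    upper <- upper.tri(p)
    present <- stats::runif(sum(upper)) < p[upper]
    weight <- ifelse(present, stats::runif(sum(upper), 0.5, 1), 0)
    m <- matrix(0, n, n)
    m[upper] <- weight
    m + t(m)
  })

  cereb <- node_table$is_cerebellar
  if (cerebellar_boost > 1 && any(cereb)) {
    w[cereb, cereb] <- w[cereb, cereb] * cerebellar_boost
  }

  cortical <- which(cortical_mask(node_table))
  n_hubs <- ceiling(hub_fraction * length(cortical))
  hubs <- integer(0)
  if (n_hubs > 0 && length(cortical) > 0) {
    # round-robin across cortical communities so every community holds hubs
    ord <- cortical[order(stats::ave(seq_along(cortical), comm[cortical],
                                     FUN = seq_along), comm[cortical])]
    hubs <- ord[seq_len(min(n_hubs, length(ord)))]
    boost <- rep(1, n)
    boost[hubs] <- hub_boost
    w <- w * outer(boost, boost)
  }
  diag(w) <- 0
  attr(w, "hubs") <- node_table$node_id[hubs]
  w
}

#' Generate a synthetic regional tau (binding potential) map
#'
#' Produces one per-node vector of tau-PET binding potential values under one
#' of three planted regimes. In `AD` mode tau is coupled to baseline nodal
#' connectivity strength (the trans-neuronal-spread signature:
#' `tau_i = beta0 + beta1 * burden * s_i / mean(s) + noise`, with `s` the base
#' strength over non-cerebellar nodes). In `PSP` mode tau is restricted to
#' subcortical nodes (`tau_i = beta0 + beta1 * burden * [subcortical] + noise`).
#' In `CTRL` mode tau is baseline plus noise. Cerebellar nodes are the PET
#' reference region and are forced to 0; all values are floored at 0.
#'
#' @param node_table node metadata
#' @param mode one of `"AD"`, `"PSP"`, `"CTRL"`
#' @param burden_param latent disease severity in \[0, 1\]
#' @param base_strengths per-node baseline connectivity strength
#' @param beta0 binding-potential offset
#' @param beta1 burden coupling strength
#' @param sigma noise standard deviation (>= 0)
#' @param seed integer seed
#' @return numeric vector of per-node binding potential values
#' @export
generate_tau_map <- function(node_table, mode, burden_param, base_strengths,
                             beta0 = 0.5, beta1 = 0.8, sigma = 0.05, seed = 1) {
  validate_node_table(node_table)
  if (!mode %in% c("AD", "PSP", "CTRL")) stop_arg("unknown mode: ", mode)
  if (sigma < 0) stop_arg("sigma must be >= 0")
  if (burden_param < 0 || burden_param > 1) stop_arg("burden_param must lie in [0, 1]")
  n <- nrow(node_table)
  if (length(base_strengths) != n) stop_arg("base_strengths length must match node table")

  noncereb <- !node_table$is_cerebellar
  signal <- switch(mode,
    AD = {
      s_mean <- mean(base_strengths[noncereb])
      if (s_mean <= 0) stop_arg("base strengths must have positive mean in AD mode")
      beta1 * burden_param * base_strengths / s_mean
    },
    PSP = beta1 * burden_param * as.numeric(node_table$is_subcortical),
    CTRL = rep(0, n)
  )
  eps <- if (sigma > 0) with_seed(seed, stats::rnorm(n, 0, sigma)) else rep(0, n)
  tau <- beta0 + signal + eps
  tau[tau < 0] <- 0
  tau[node_table$is_cerebellar] <- 0
  tau
}

#' Modulate a subject's connectivity by tau burden
#'
#' Applies the planted disease effect of tau on functional connections.
#' `AD` mode weakens edges in proportion to the mean tau of their endpoints:
#' `w_ij <- w_ij * (1 - gamma * burden * (tau_i + tau_j) / 2)`. `PSP` mode
#' strengthens cortico-cortical edges by `(1 + gamma * burden)` and weakens any
#' edge touching a subcortical node by `(1 - gamma * burden)`; edges confined
#' to the cerebellum are untouched. `CTRL` returns the base network unchanged.
#'
#' @param base symmetric base weight matrix
#' @param node_table node metadata
#' @param mode one of `"AD"`, `"PSP"`, `"CTRL"`
#' @param burden_param latent severity in \[0, 1\]
#' @param tau per-node binding potential vector
#' @param gamma modulation strength; requires `gamma * burden_param * max(tau) < 1`
#' @return modulated symmetric weight matrix (zero diagonal preserved)
#' @export
modulate_subject_network <- function(base, node_table, mode, burden_param,
                                     tau, gamma) {
  validate_node_table(node_table)
  check_square_symmetric(base, what = "base network")
  if (!mode %in% c("AD", "PSP", "CTRL")) stop_arg("unknown mode: ", mode)
  if (length(tau) != nrow(base)) stop_arg("tau length must match network dimension")
  if (gamma * burden_param * max(tau) >= 1) {
    stop_arg("gamma * burden_param * max(tau) must be < 1 to keep weights positive")
  }
  factor <- switch(mode,
    AD = 1 - gamma * burden_param * outer(tau, tau, function(a, b) (a + b) / 2),
    PSP = {
      cort <- cortical_mask(node_table)
      sub <- node_table$is_subcortical
      f <- matrix(1, nrow(base), ncol(base))
      f[cort, cort] <- 1 + gamma * burden_param
      touches_sub <- outer(sub, sub, "|")
      f[touches_sub] <- 1 - gamma * burden_param
      f
    },
    CTRL = matrix(1, nrow(base), ncol(base))
  )
  out <- base * factor
  out <- (out + t(out)) / 2
  diag(out) <- 0
  attr(out, "hubs") <- attr(base, "hubs")
  out
}

#' Sample node time series from a planted covariance
#'
#' Draws `t_points` independent samples from a zero-mean multivariate Gaussian
#' with covariance `Sigma = load * W / max(rowSums(W)) + I`. Scaling by the
#' maximum row sum makes `Sigma` strictly diagonally dominant for
#' `load < 1`, hence positive definite. Samples are i.i.d. over time: the
#' generator targets the correlation matrix consumed downstream, not BOLD
#' temporal dynamics.
#'
#' @param weights symmetric non-negative weight matrix, zero diagonal
#' @param t_points number of time points (>= 2)
#' @param load coupling strength in (0, 1)
#' @param seed integer seed
#' @return node x time numeric matrix
#' @export
sample_timeseries <- function(weights, t_points, load = 0.98, seed = 1) {
  check_square_symmetric(weights, what = "weights")
  if (any(weights < 0)) stop_arg("weights must be non-negative")
  if (any(diag(weights) != 0)) stop_arg("weights must have zero diagonal")
  if (t_points < 2) stop_arg("t_points must be >= 2")
  if (load <= 0 || load >= 1) stop_arg("load must lie in (0, 1)")
  n <- nrow(weights)
  max_row <- max(rowSums(weights))
  sigma <- if (max_row > 0) load * weights / max_row else matrix(0, n, n)
  diag(sigma) <- diag(sigma) + 1
  cf <- chol(sigma)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * t_points), nrow = n, ncol = t_points)
    crossprod(cf, z)  # t(cf) %*% z has covariance sigma column-wise
  })
}

#' Default synthetic-cohort configuration
#'
#' Returns the generator settings used throughout the package: a 130-node
#' parcellation (100 cortical nodes in 4 communities, 20 subcortical, 10
#' cerebellar), 250 time points per subject, and group sizes 17 (AD),
#' 17 (PSP), 12 (controls). Latent disease burden is uniform on \[0, 0.1\] for
#' controls and \[0.1, 1\] for the disease groups.
#'
#' @param ... named overrides of any default field
#' @return a named list of generator settings
#' @export
cohort_config <- function(...) {
  config <- list(
    n_cortical = 100, n_communities = 4, n_subcortical = 20, n_cerebellar = 10,
    group_sizes = c(AD = 17, PSP = 17, CTRL = 12),
    t_points = 250, load = 0.98,
    p_in = 0.25, p_out = 0.02, hub_fraction = 0.1, hub_boost = 1.2,
    cerebellar_boost = 4,
    beta0 = 0.5, beta1 = 0.8, sigma = 0.05, gamma = 0.4,
    burden_range = list(AD = c(0.1, 1), PSP = c(0.1, 1), CTRL = c(0, 0.1)),
    age_mean = 70, age_sd = 7,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    stop_arg("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  config[names(overrides)] <- overrides
  config
}

#' Generate a full synthetic cohort
#'
#' Builds the node table and base network once, then for every subject draws a
#' latent burden, a tau map, a burden-modulated connectivity matrix and a node
#' x time series. All per-subject seeds are derived deterministically from
#' `config$seed`, so equal configurations regenerate bit-identical bundles.
#'
#' @param config settings from [cohort_config()]
#' @return a `cohort_bundle`: list with `node_table`, `subjects` (data.frame
#'   with `subject_id`, `group`, `age`, `burden_param`), `timeseries` (named
#'   list of node x time matrices), `tau` (subject x node matrix), and `truth`
#'   (all planted parameters and seeds)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (any(config$group_sizes < 1)) stop_arg("all group sizes must be >= 1")
  # independent per-stage seed streams derived from the master seed
  stage_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, 3L))
  node_table <- make_node_table(config$n_cortical, config$n_communities,
                                config$n_subcortical, config$n_cerebellar,
                                seed = stage_seeds[1])
  base <- make_base_network(node_table, p_in = config$p_in, p_out = config$p_out,
                            hub_fraction = config$hub_fraction,
                            hub_boost = config$hub_boost,
                            cerebellar_boost = config$cerebellar_boost,
                            seed = stage_seeds[2])
  base_strengths <- rowSums(base)

  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n_subj <- length(groups)
  draws <- with_seed(stage_seeds[3], {
    list(
      seeds = sample.int(.Machine$integer.max - 1L, 2L * n_subj),
      u = stats::runif(n_subj),
      age = pmax(40, stats::rnorm(n_subj, config$age_mean, config$age_sd))
    )
  })
  burden <- vapply(seq_len(n_subj), function(j) {
    rng <- config$burden_range[[groups[j]]]
    rng[1] + draws$u[j] * (rng[2] - rng[1])
  }, numeric(1))

  subject_id <- sprintf("%s_%02d", groups, stats::ave(seq_len(n_subj), groups,
                                                      FUN = seq_along))
  n_nodes <- nrow(node_table)
  tau <- matrix(0, n_subj, n_nodes,
                dimnames = list(subject_id, node_table$node_id))
  timeseries <- vector("list", n_subj)
  names(timeseries) <- subject_id
  for (j in seq_len(n_subj)) {
    tau[j, ] <- generate_tau_map(node_table, mode = groups[j],
                                 burden_param = burden[j],
                                 base_strengths = base_strengths,
                                 beta0 = config$beta0, beta1 = config$beta1,
                                 sigma = config$sigma,
                                 seed = draws$seeds[2 * j - 1])
    w <- modulate_subject_network(base, node_table, mode = groups[j],
                                  burden_param = burden[j], tau = tau[j, ],
                                  gamma = config$gamma)
    timeseries[[j]] <- sample_timeseries(w, config$t_points, load = config$load,
                                         seed = draws$seeds[2 * j])
  }

  subjects <- data.frame(subject_id = subject_id, group = groups,
                         age = draws$age, burden_param = burden,
                         stringsAsFactors = FALSE)
  bundle <- list(
    node_table = node_table,
    subjects = subjects,
    timeseries = timeseries,
    tau = tau,
    truth = list(config = config, base_strengths = base_strengths,
                 hubs = attr(base, "hubs"), subject_seeds = draws$seeds,
                 burden = burden)
  )
  class(bundle) <- "cohort_bundle"
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects,",
      nrow(x$node_table), "nodes,", ncol(x$timeseries[[1]]), "time points\n")
  print(table(x$subjects$group))
  invisible(x)
}
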