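# Statistics linking regional tau binding potential to connectome graph
# properties: Jennrich matrix-equality test, subject burden summaries,
# moderation (interaction) regression, node-wise gradient maps and sign tests.

cor_result <- function(x, y) {
  if (length(x) != length(y)) stop_arg("vectors must have equal length")
  if (length(x) < 3) stop_arg("at least 3 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_arg("constant input: correlation undefined")
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  structure(
    list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
         spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
         n = length(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (p = %.3g), Spearman rho = %.3f (p = %.3g), n = %d\n",
              x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p, x$n))
  invisible(x)
}

#' Jennrich test for equality of two correlation matrices
#'
#' Chi-squared test of the null hypothesis that two sample correlation
#' matrices estimate the same population correlation matrix, following
#' Jennrich (1970). With pooled matrix `Rbar = (n1 R1 + n2 R2)/(n1 + n2)`
#' (plus `ridge * I` when `ridge > 0`),
#' `Z = sqrt(n1 n2 / (n1 + n2)) * Rbar^{-1} (R1 - R2)` and
#' `chi2 = tr(Z^2)/2 - diag(Z)' S^{-1} diag(Z)` with
#' `S_ij = delta_ij + Rbar_ij * (Rbar^{-1})_ij`, on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param R1,R2 correlation matrices of equal dimension, unit diagonal
#' @param n1,n2 observation counts behind each matrix (>= 2)
#' @param ridge non-negative diagonal loading added to the pooled matrix when
#'   it is singular or near-singular (flagged in the result)
#' @return a `jennrich_result`: list with `chi2`, `df`, `p_value`, `n1`, `n2`,
#'   `ridge`
#' @export
jennrich_test <- function(R1, n1, R2, n2, ridge = 0) {
  check_square_symmetric(R1, tol = 1e-8, what = "R1")
  check_square_symmetric(R2, tol = 1e-8, what = "R2")
  if (!all(dim(R1) == dim(R2))) stop_arg("R1 and R2 must share dimensions")
  if (max(abs(diag(R1) - 1)) > 1e-8 || max(abs(diag(R2) - 1)) > 1e-8) {
    stop_arg("correlation matrices must have unit diagonals")
  }
  if (n1 < 2 || n2 < 2) stop_arg("n1 and n2 must be >= 2")
  if (ridge < 0) stop_arg("ridge must be non-negative")
  p <- nrow(R1)
  rbar <- (n1 * R1 + n2 * R2) / (n1 + n2)
  if (ridge > 0) rbar <- rbar + ridge * diag(p)
  rbar_inv <- tryCatch(solve(rbar), error = function(e) NULL)
  if (is.null(rbar_inv)) {
    stop_arg("pooled correlation matrix is singular; supply ridge > 0 or ",
             "reduce the node set")
  }
  cc <- n1 * n2 / (n1 + n2)
  zmat <- sqrt(cc) * rbar_inv %*% (R1 - R2)
  s <- diag(p) + rbar * rbar_inv
  dg <- diag(zmat)
  chi2 <- sum(diag(zmat %*% zmat)) / 2 -
    as.numeric(t(dg) %*% solve(s, dg))
  chi2 <- max(chi2, 0)
  df <- p * (p - 1) / 2
  structure(
    list(chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
         n1 = n1, n2 = n2, ridge = ridge),
    class = "jennrich_result"
  )
}

#' @export
print.jennrich_result <- function(x, ...) {
  cat(sprintf("Jennrich chi2 = %.4g, df = %d, p = %.3g (n1 = %d, n2 = %d%s)\n",
              x$chi2, x$df, x$p_value, x$n1, x$n2,
              if (x$ridge > 0) sprintf(", ridge = %g", x$ridge) else ""))
  invisible(x)
}

#' Per-subject tau burden
#'
#' Summarizes each subject's regional binding-potential map into a single
#' burden scalar: the mean over all non-cerebellar nodes (`"whole_brain"`,
#' suited to diseases with distributed cortical tau) or over the subcortical
#' node set (`"subcortical"`, suited to diseases with deep-nuclei-restricted
#' tau).
#'
#' @param tau subject x node binding-potential matrix
#' @param node_table node metadata
#' @param method `"whole_brain"` or `"subcortical"`
#' @return a `burden_vector`: list with `values` (named per-subject) and
#'   `method`
#' @export
subject_tau_burden <- function(tau, node_table,
                               method = c("whole_brain", "subcortical")) {
  method <- match.arg(method)
  validate_node_table(node_table)
  if (ncol(tau) != nrow(node_table)) stop_arg("tau columns must match node table")
  mask <- if (method == "whole_brain") {
    !node_table$is_cerebellar
  } else {
    node_table$is_subcortical
  }
  if (!any(mask)) stop_arg("no qualifying nodes for method ", method)
  structure(
    list(values = rowMeans(tau[, mask, drop = FALSE]), method = method,
         age_residualized = FALSE),
    class = "burden_vector"
  )
}

#' Residualize tau burden on age
#'
#' Replaces burden values with the residuals of an ordinary least-squares
#' regression of burden on age (intercept included), removing the linear age
#' effect before downstream models.
#'
#' @param burden a `burden_vector`
#' @param ages per-subject ages (same order and length)
#' @return a `burden_vector` with residualized values and
#'   `age_residualized = TRUE`
#' @export
partial_out_age <- function(burden, ages) {
  v <- burden$values
  if (length(ages) != length(v)) stop_arg("ages must match burden length")
  if (length(v) < 3) stop_arg("at least 3 subjects are required")
  if (stats::sd(ages) == 0) stop_arg("constant age vector")
  fit <- stats::lm(v ~ ages)
  out <- burden
  out$values <- stats::setNames(as.numeric(stats::residuals(fit)), names(v))
  out$age_residualized <- TRUE
  out
}

#' Node-wise correlation between a group-mean metric and group-mean tau
#'
#' @param group_metric per-node group-averaged metric values
#' @param group_tau per-node group-averaged binding potential
#' @param node_mask logical or integer subset of nodes to use (>= 3 nodes)
#' @return a `correlation_result`
#' @export
nodewise_metric_tau_correlation <- function(group_metric, group_tau,
                                            node_mask = NULL) {
  if (length(group_metric) != length(group_tau)) {
    stop_arg("metric and tau vectors must have equal length")
  }
  if (is.null(node_mask)) node_mask <- seq_along(group_metric)
  x <- group_metric[node_mask]
  y <- group_tau[node_mask]
  cor_result(x, y)
}

#' Assign nodes to intrinsic connectivity networks
#'
#' A node joins a network when any voxel of that network's spatial map with
#' value `>= z_threshold` lies within `radius_mm` (inclusive) of the node
#' centroid. Voxel indices are 0-based and mapped to mm through the 4x4
#' `affine`. Multiple memberships are allowed; memberships are written to the
#' `networks` column as a comma-separated string.
#'
#' @param node_table node metadata with centroid columns `x`, `y`, `z`
#' @param network_masks named list of 3D numeric arrays (one per network)
#' @param z_threshold voxel inclusion threshold (default 2.6)
#' @param radius_mm membership radius in mm, inclusive (default 5)
#' @param affine 4x4 voxel-to-mm affine
#' @return the node table with an updated `networks` column
#' @export
assign_nodes_to_networks <- function(node_table, network_masks,
                                     z_threshold = 2.6, radius_mm = 5,
                                     affine = NULL) {
  validate_node_table(node_table)
  if (is.null(affine) || !is.matrix(affine) || !all(dim(affine) == c(4, 4))) {
    stop_arg("a 4x4 voxel-to-mm affine is required")
  }
  if (is.null(names(network_masks)) || any(names(network_masks) == "")) {
    stop_arg("network_masks must be a named list")
  }
  centroids <- as.matrix(node_table[, c("x", "y", "z")])
  membership <- vector("list", nrow(node_table))
  for (net in names(network_masks)) {
    vol <- network_masks[[net]]
    hits <- which(vol >= z_threshold, arr.ind = TRUE)
    if (nrow(hits) == 0) next
    vox_mm <- t(affine %*% rbind(t(hits - 1), 1))[, 1:3, drop = FALSE]
    for (i in seq_len(nrow(node_table))) {
      d2 <- rowSums((vox_mm - matrix(centroids[i, ], nrow(vox_mm), 3,
                                     byrow = TRUE))^2)
      if (min(d2) <= radius_mm^2) {
        membership[[i]] <- c(membership[[i]], net)
      }
    }
  }
  node_table$networks <- vapply(membership, function(m) {
    paste(m, collapse = ",")
  }, character(1))
  node_table
}

#' Within-group regression of a subject-level metric on tau burden
#'
#' @param burden a `burden_vector` (or numeric vector) for one group
#' @param subject_metric_means per-subject whole-brain metric averages
#' @return list with `slope` (OLS slope of metric on burden) and `cor`
#'   (a `correlation_result`)
#' @export
burden_metric_regression <- function(burden, subject_metric_means) {
  b <- if (inherits(burden, "burden_vector")) burden$values else burden
  if (length(b) != length(subject_metric_means)) {
    stop_arg("burden and metric vectors must have equal length")
  }
  if (length(b) < 3) stop_arg("at least 3 subjects are required")
  if (stats::sd(subject_metric_means) == 0) {
    stop_arg("constant metric values: regression degenerate")
  }
  if (stats::sd(b) == 0) stop_arg("constant burden values: regression degenerate")
  slope <- stats::cov(b, subject_metric_means) / stats::var(b)
  list(slope = slope, cor = cor_result(b, subject_metric_means))
}

#' Moderation analysis: does the burden-metric slope differ between groups?
#'
#' Fits `metric ~ burden + group + burden:group` by OLS with a 0/1 group
#' indicator and compares it to the model without the interaction.
#' `delta_r2 = R2(full) - R2(reduced)` is the variance uniquely explained by
#' the slope difference; `F = delta_r2 * (n - 4) / (1 - R2(full))` on
#' `(1, n - 4)` degrees of freedom.
#'
#' @param burden per-subject burden over both groups (`burden_vector` or
#'   numeric)
#' @param metric_means per-subject metric values
#' @param group_labels two-level factor/character/binary vector
#' @return a `moderation_result`: list with `delta_r2`, `f_stat`, `df1`,
#'   `df2`, `p_value`, `n`, `slopes` (per-group burden slopes)
#' @export
moderation_analysis <- function(burden, metric_means, group_labels) {
  b <- if (inherits(burden, "burden_vector")) burden$values else burden
  n <- length(b)
  if (length(metric_means) != n || length(group_labels) != n) {
    stop_arg("all inputs must have equal length")
  }
  levels_g <- unique(group_labels)
  if (length(levels_g) != 2) stop_arg("exactly two groups are required")
  if (n < 6) stop_arg("at least 6 subjects are required")
  g <- as.numeric(group_labels == levels_g[2])
  x <- as.numeric(b)
  y <- as.numeric(metric_means)
  design_full <- cbind(1, x, g, x * g)
  if (qr(design_full)$rank < 4) stop_arg("rank-deficient design matrix")
  fit_full <- stats::lm(y ~ x + g + x:g)
  fit_red <- stats::lm(y ~ x + g)
  r2_full <- summary(fit_full)$r.squared
  r2_red <- summary(fit_red)$r.squared
  delta_r2 <- r2_full - r2_red
  df2 <- n - 4
  f_stat <- delta_r2 * df2 / (1 - r2_full)
  coefs <- stats::coef(fit_full)
  structure(
    list(delta_r2 = delta_r2, f_stat = f_stat, df1 = 1, df2 = df2,
         p_value = stats::pf(f_stat, 1, df2, lower.tail = FALSE), n = n,
         slopes = stats::setNames(c(coefs["x"], coefs["x"] + coefs["x:g"]),
                                  as.character(levels_g))),
    class = "moderation_result"
  )
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("Moderation: delta r2 = %.3f, F(%d,%d) = %.2f, p = %.3g\n",
              x$delta_r2, x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}

#' Node-wise gradient map of a metric against tau burden
#'
#' For each non-cerebellar node, the OLS slope of the subject-level metric
#' value at that node on subject tau burden, within one group. The slope
#' ("gradient") measures the local disease-related change in the metric per
#' unit burden.
#'
#' @param metric_panel subject x node matrix of metric values for the group
#' @param burden a `burden_vector` (or numeric) for the same subjects
#' @param node_table node metadata (cerebellar nodes are dropped)
#' @return a `gradient_map`: list with `slopes` (named by node_id, cerebellar
#'   nodes absent) and `node_ids`
#' @export
nodal_gradient_map <- function(metric_panel, burden, node_table) {
  b <- if (inherits(burden, "burden_vector")) burden$values else burden
  validate_node_table(node_table)
  if (!is.matrix(metric_panel) || ncol(metric_panel) != nrow(node_table)) {
    stop_arg("metric_panel must be subjects x nodes matching the node table")
  }
  if (nrow(metric_panel) != length(b)) stop_arg("subject counts must match")
  if (length(b) < 3) stop_arg("at least 3 subjects are required")
  if (stats::sd(b) == 0) stop_arg("constant burden: gradients undefined")
  keep <- !node_table$is_cerebellar
  bc <- b - mean(b)
  slopes <- as.numeric(crossprod(bc, metric_panel[, keep, drop = FALSE])) /
    sum(bc^2)
  structure(
    list(slopes = stats::setNames(slopes, node_table$node_id[keep]),
         node_ids = node_table$node_id[keep]),
    class = "gradient_map"
  )
}

#' Sign test on a gradient map
#'
#' Tests whether positive and negative nodal gradients are balanced. With `k`
#' positive slopes among `n` nonzero ones, `Z = (2k - n) / sqrt(n)`; the
#' p-value is the exact two-sided binomial probability (doubled smaller tail,
#' capped at 1). Zero slopes are excluded and counted.
#'
#' @param gradients a `gradient_map` or numeric vector of slopes
#' @return list with `z`, `p_value`, `n_nonzero`, `n_zero`, `k_positive`
#' @export
sign_test <- function(gradients) {
  slopes <- if (inherits(gradients, "gradient_map")) gradients$slopes else gradients
  nonzero <- slopes[slopes != 0]
  n_zero <- sum(slopes == 0)
  n <- length(nonzero)
  if (n == 0) stop_arg("all slopes are zero: sign test undefined")
  k <- sum(nonzero > 0)
  z <- (2 * k - n) / sqrt(n)
  m <- min(k, n - k)
  p <- min(1, 2 * stats::pbinom(m, n, 0.5))
  list(z = z, p_value = p, n_nonzero = n, n_zero = n_zero, k_positive = k)
}

#' Correlate a gradient map with group-mean nodal tau
#'
#' @param gradients a `gradient_map`
#' @param group_tau_mean per-node group-averaged binding potential (full node
#'   set; cerebellar nodes are dropped to match the gradient map)
#' @param node_table node metadata
#' @return a `correlation_result`
#' @export
gradient_tau_correlation <- function(gradients, group_tau_mean, node_table) {
  validate_node_table(node_table)
  if (length(group_tau_mean) != nrow(node_table)) {
    stop_arg("group_tau_mean must cover the full node set")
  }
  keep <- !node_table$is_cerebellar
  tau <- group_tau_mean[keep]
  slopes <- gradients$slopes
  if (length(slopes) != sum(keep)) {
    stop_arg("gradient map does not match the non-cerebellar node set")
  }
  cor_result(slopes, tau)
}
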