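# End-to-end analysis over a cohort bundle: association matrices, thresholded
# graphs, nodal metrics, and the tau-network statistical battery. This is the
# computational core behind the analysis/ driver scripts.

#' Per-subject association matrices
#'
#' @param bundle a `cohort_bundle`
#' @return named list of Fisher-z association matrices
#' @export
cohort_association_matrices <- function(bundle) {
  lapply(bundle$timeseries, compute_association_matrix)
}

subject_metric_matrix <- function(values_by_subject, subject_ids, n_nodes) {
  m <- do.call(rbind, values_by_subject)
  rownames(m) <- subject_ids
  stopifnot(ncol(m) == n_nodes)
  m
}

#' Run the full tau-network analysis on a cohort
#'
#' Computes, for every subject: the Fisher-z association matrix, the
#' thresholded graph at `density`, nodal strength, and the requested nodal
#' metrics (with optional null-model normalization of binarized metrics when
#' `n_random > 0`). Then runs the group-level battery: node-wise metric-tau
#' correlations over group averages, per-group burden-metric regressions,
#' AD-vs-PSP moderation, per-group nodal gradient maps with sign tests and
#' gradient-tau correlations, and Jennrich tests between group-averaged
#' association matrices (on a node subset and/or with ridge, since the full
#' pooled matrix is singular when nodes far outnumber subjects).
#'
#' @param bundle a `cohort_bundle`
#' @param density edge density for thresholding (default 0.06)
#' @param metrics node-level metrics to analyse; any of `"weighted_degree"`,
#'   `"participation"`, `"clustering"`, `"betweenness"`, `"closeness"`,
#'   `"local_efficiency"`, `"eigenvector"`
#' @param n_random null-ensemble size for normalizing binarized metrics
#'   (0 analyses them raw)
#' @param seed seed for Louvain and the null ensembles
#' @param burden_methods named character vector mapping group to burden method
#' @param age_partial residualize burden on age before subject-level models
#' @param jennrich_nodes number of evenly spaced non-cerebellar nodes for the
#'   Jennrich tests (NULL uses all non-cerebellar nodes)
#' @param jennrich_ridge ridge added to the pooled Jennrich matrix
#' @param rank_by edge ranking rule for thresholding
#' @return list with `assoc` (per-subject matrices), `group_average`
#'   (per-group mean z matrices), `metric_values` (per-metric subject x node
#'   matrices), `strength`, `burden`, `nodewise`, `burden_regression`,
#'   `moderation`, `gradients`, `sign_tests`, `gradient_tau`, `jennrich`,
#'   and `results` (one tidy data.frame of all statistics)
#' @export
run_cohort_analysis <- function(bundle,
                                density = 0.06,
                                metrics = c("weighted_degree", "participation"),
                                n_random = 0,
                                seed = 1,
                                burden_methods = c(AD = "whole_brain",
                                                   PSP = "subcortical",
                                                   CTRL = "whole_brain"),
                                age_partial = FALSE,
                                jennrich_nodes = 50,
                                jennrich_ridge = 0,
                                rank_by = "signed") {
  node_table <- bundle$node_table
  validate_node_table(node_table)
  subjects <- bundle$subjects
  groups <- unique(subjects$group)
  n_nodes <- nrow(node_table)
  noncereb <- !node_table$is_cerebellar
  known <- c("weighted_degree", "participation", "clustering", "betweenness",
             "closeness", "local_efficiency", "eigenvector")
  bad <- setdiff(metrics, known)
  if (length(bad) > 0) stop_arg("unknown metrics: ", paste(bad, collapse = ", "))

  assoc <- cohort_association_matrices(bundle)
  graphs <- lapply(assoc, threshold_graph, density = density, rank_by = rank_by)
  strength <- subject_metric_matrix(lapply(assoc, nodal_strength),
                                    subjects$subject_id, n_nodes)

  binary_metrics <- intersect(metrics,
                              c("clustering", "betweenness", "closeness",
                                "local_efficiency", "eigenvector"))
  metric_values <- list()
  for (m in metrics) metric_values[[m]] <- vector("list", nrow(subjects))
  for (j in seq_len(nrow(subjects))) {
    g <- graphs[[j]]
    if ("weighted_degree" %in% metrics) {
      metric_values$weighted_degree[[j]] <- weighted_degree(g)
    }
    if ("participation" %in% metrics) {
      part <- louvain_partition(g, seed = seed)
      metric_values$participation[[j]] <- participation_coefficient(g, part)
    }
    if (length(binary_metrics) > 0) {
      funs <- binary_metric_funs()
      names(funs) <- c("clustering", "betweenness", "closeness",
                       "local_efficiency", "eigenvector")
      raw <- lapply(funs[binary_metrics], function(f) f(g$binary))
      if (n_random > 0) {
        ens <- random_ensemble(g$binary, n_random = n_random, seed = seed + j)
        for (m in binary_metrics) {
          metric_values[[m]][[j]] <- as.numeric(
            normalize_metric(raw[[m]], ens, m))
        }
      } else {
        for (m in binary_metrics) metric_values[[m]][[j]] <- raw[[m]]
      }
    }
  }
  metric_values <- lapply(metric_values, subject_metric_matrix,
                          subject_ids = subjects$subject_id, n_nodes = n_nodes)

  group_average <- lapply(stats::setNames(groups, groups), function(gr) {
    group_average_matrix(assoc[subjects$group == gr])
  })
  group_tau_mean <- lapply(stats::setNames(groups, groups), function(gr) {
    colMeans(bundle$tau[subjects$group == gr, , drop = FALSE])
  })

  burden <- lapply(stats::setNames(groups, groups), function(gr) {
    in_g <- subjects$group == gr
    bv <- subject_tau_burden(bundle$tau[in_g, , drop = FALSE], node_table,
                             method = burden_methods[[gr]])
    if (age_partial) bv <- partial_out_age(bv, subjects$age[in_g])
    bv
  })

  rows <- list()
  add_row <- function(analysis, group, metric, statistic, value, p = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, group = group, metric = metric, density = density,
      statistic = statistic, value = value, p = p, stringsAsFactors = FALSE)
  }

  nodewise <- list()
  burden_regression <- list()
  gradients <- list()
  sign_tests <- list()
  gradient_tau <- list()
  for (m in metrics) {
    for (gr in groups) {
      in_g <- subjects$group == gr
      gm <- colMeans(metric_values[[m]][in_g, , drop = FALSE])
      cr <- nodewise_metric_tau_correlation(gm, group_tau_mean[[gr]],
                                            node_mask = noncereb)
      nodewise[[paste(m, gr, sep = ".")]] <- cr
      add_row("nodewise_tau_correlation", gr, m, "pearson_r", cr$pearson_r,
              cr$pearson_p)
      add_row("nodewise_tau_correlation", gr, m, "spearman_rho",
              cr$spearman_rho, cr$spearman_p)

      subj_mean <- rowMeans(metric_values[[m]][in_g, noncereb, drop = FALSE])
      reg <- burden_metric_regression(burden[[gr]], subj_mean)
      burden_regression[[paste(m, gr, sep = ".")]] <- reg
      add_row("burden_regression", gr, m, "slope", reg$slope)
      add_row("burden_regression", gr, m, "pearson_r", reg$cor$pearson_r,
              reg$cor$pearson_p)

      gmap <- nodal_gradient_map(metric_values[[m]][in_g, , drop = FALSE],
                                 burden[[gr]], node_table)
      gradients[[paste(m, gr, sep = ".")]] <- gmap
      st <- sign_test(gmap)
      sign_tests[[paste(m, gr, sep = ".")]] <- st
      add_row("sign_test", gr, m, "z", st$z, st$p_value)
      gt <- gradient_tau_correlation(gmap, group_tau_mean[[gr]], node_table)
      gradient_tau[[paste(m, gr, sep = ".")]] <- gt
      add_row("gradient_tau_correlation", gr, m, "pearson_r", gt$pearson_r,
              gt$pearson_p)
    }
  }

  moderation <- list()
  if (all(c("AD", "PSP") %in% groups)) {
    in_ad <- subjects$group == "AD"
    in_psp <- subjects$group == "PSP"
    b_both <- c(burden$AD$values, burden$PSP$values)
    g_both <- c(rep("AD", sum(in_ad)), rep("PSP", sum(in_psp)))
    for (m in metrics) {
      y <- c(rowMeans(metric_values[[m]][in_ad, noncereb, drop = FALSE]),
             rowMeans(metric_values[[m]][in_psp, noncereb, drop = FALSE]))
      mod <- moderation_analysis(b_both, y, g_both)
      moderation[[m]] <- mod
      add_row("moderation", "AD_vs_PSP", m, "delta_r2", mod$delta_r2,
              mod$p_value)
      add_row("moderation", "AD_vs_PSP", m, "f_stat", mod$f_stat, mod$p_value)
    }
  }

  jennrich <- list()
  if (length(groups) >= 2) {
    subset_nodes <- which(noncereb)
    if (!is.null(jennrich_nodes) && jennrich_nodes < length(subset_nodes)) {
      subset_nodes <- subset_nodes[
        round(seq(1, length(subset_nodes), length.out = jennrich_nodes))]
    }
    to_corr <- function(zbar) {
      r <- tanh(zbar[subset_nodes, subset_nodes])
      diag(r) <- 1
      r
    }
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in pairs) {
      n1 <- sum(subjects$group == pr[1])
      n2 <- sum(subjects$group == pr[2])
      jr <- jennrich_test(to_corr(group_average[[pr[1]]]), n1,
                          to_corr(group_average[[pr[2]]]), n2,
                          ridge = jennrich_ridge)
      key <- paste(pr, collapse = "_vs_")
      jennrich[[key]] <- jr
      add_row("jennrich", key, "association_matrix", "chi2", jr$chi2,
              jr$p_value)
    }
  }

  list(
    assoc = assoc,
    group_average = group_average,
    group_tau_mean = group_tau_mean,
    metric_values = metric_values,
    strength = strength,
    burden = burden,
    nodewise = nodewise,
    burden_regression = burden_regression,
    moderation = moderation,
    gradients = gradients,
    sign_tests = sign_tests,
    gradient_tau = gradient_tau,
    jennrich = jennrich,
    results = do.call(rbind, rows)
  )
}
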