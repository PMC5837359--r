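test_that("jennrich statistic is zero for identical matrices and df is p(p-1)/2", {
  r <- ar1_corr(5)
  res <- jennrich_test(r, 20, r, 30)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  expect_equal(jennrich_test(ar1_corr(3), 10, ar1_corr(3, 0.1), 10)$df, 3)
  expect_equal(res$df, 10)

  expect_error(jennrich_test(r, 1, r, 10), "n1 and n2")
  bad <- r
  diag(bad) <- 2
  expect_error(jennrich_test(bad, 10, bad, 10), "unit diagonal")
})

test_that("jennrich detects genuinely different correlation structures", {
  set.seed(1)
  r1 <- sample_corr(200, chol(ar1_corr(5, 0.0)))
  r2 <- sample_corr(200, chol(ar1_corr(5, 0.7)))
  res <- jennrich_test(r1, 200, r2, 200)
  expect_lt(res$p_value, 1e-6)
})

test_that("singular pooled matrices demand a ridge", {
  p <- 6
  # rank-1 degenerate matrix: pooled matrix singular without a ridge
  ones <- matrix(1, p, p)
  expect_error(jennrich_test(ones, 5, ones, 5), "singular")
  res <- jennrich_test(ones, 5, ones, 5, ridge = 0.01)
  expect_equal(res$ridge, 0.01)
})

test_that("subject tau burden averages the configured node sets", {
  nt <- make_node_table(100, 4, 20, 10, seed = 1)
  n <- nrow(nt)
  tau <- matrix(0.4, 2, n)
  tau[, nt$is_cerebellar] <- 0
  wb <- subject_tau_burden(tau, nt, "whole_brain")
  sc <- subject_tau_burden(tau, nt, "subcortical")
  expect_equal(unname(wb$values), c(0.4, 0.4))
  expect_equal(unname(sc$values), c(0.4, 0.4))

  tau2 <- matrix(0, 1, n)
  tau2[, nt$is_subcortical] <- 1
  expect_equal(unname(subject_tau_burden(tau2, nt, "whole_brain")$values),
               20 / 120)
  expect_equal(unname(subject_tau_burden(tau2, nt, "subcortical")$values), 1)

  no_sub <- make_node_table(10, 2, 0, 2, seed = 1)
  expect_error(subject_tau_burden(matrix(1, 1, 12), no_sub, "subcortical"),
               "qualifying")
})

test_that("subcortical burden is monotone in planted severity when noiseless", {
  nt <- make_node_table(40, 2, 10, 5, seed = 1)
  s <- rowSums(make_base_network(nt, seed = 2))
  burdens <- seq(0.1, 1, length.out = 8)
  tau <- t(vapply(burdens, function(b) {
    generate_tau_map(nt, "PSP", b, s, sigma = 0, seed = 1)
  }, numeric(nrow(nt))))
  bv <- subject_tau_burden(tau, nt, "subcortical")
  expect_true(all(diff(bv$values) > 0))
})

test_that("age partialling produces OLS residuals orthogonal to age", {
  set.seed(2)
  ages <- runif(20, 55, 85)
  bv <- structure(list(values = 2 * ages, method = "whole_brain",
                       age_residualized = FALSE), class = "burden_vector")
  res <- partial_out_age(bv, ages)
  expect_equal(unname(res$values), rep(0, 20), tolerance = 1e-10)
  expect_true(res$age_residualized)

  noise <- rnorm(20)
  bv2 <- structure(list(values = noise, method = "whole_brain",
                        age_residualized = FALSE), class = "burden_vector")
  res2 <- partial_out_age(bv2, ages)
  expect_equal(abs(cor(res2$values, ages)), 0, tolerance = 1e-10)
  expect_error(partial_out_age(bv2, rep(70, 20)), "constant age")
})

test_that("node-wise correlations report both Pearson and Spearman", {
  x <- c(1, 2, 3, 5, 8, 13)
  res <- nodewise_metric_tau_correlation(x, x)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$spearman_rho, 1)
  expect_equal(res$n, 6)
  expect_error(nodewise_metric_tau_correlation(x, rep(1, 6)), "constant")

  set.seed(3)
  ps <- replicate(200, {
    nodewise_metric_tau_correlation(rnorm(30), rnorm(30))$pearson_p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("node-network assignment applies the inclusive 5 mm rule", {
  nt <- make_node_table(4, 2, 0, 0, seed = 1)
  nt$x <- c(0, 10, 20, 30)
  nt$y <- 0
  nt$z <- 0
  affine <- diag(4)
  affine[1, 4] <- 0  # voxel (i,j,k) -> mm (i,j,k)
  vol <- array(0, dim = c(40, 3, 3))
  vol[1, 1, 1] <- 3  # suprathreshold voxel at mm (0,0,0)
  vol[16, 1, 1] <- 3  # voxel at mm (15,0,0): exactly 5.0 mm from x=10 and x=20
  out <- assign_nodes_to_networks(nt, list(dmn = vol), z_threshold = 2.6,
                                  radius_mm = 5, affine = affine)
  expect_equal(out$networks, c("dmn", "dmn", "dmn", ""))

  vol2 <- array(0, dim = c(40, 3, 3))
  vol2[17, 1, 1] <- 3  # 6 mm away from x=10: past the inclusive radius
  out2 <- assign_nodes_to_networks(nt, list(dmn = vol2), affine = affine)
  expect_equal(out2$networks[2], "")

  sub <- array(1, dim = c(2, 2, 2))  # below threshold everywhere
  out3 <- assign_nodes_to_networks(nt, list(dmn = sub), affine = affine)
  expect_equal(out3$networks, rep("", 4))
  expect_error(assign_nodes_to_networks(nt, list(dmn = vol)), "affine")
})

test_that("burden-metric regression recovers exact linear relations", {
  b <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  res <- burden_metric_regression(b, -2 * b + 5)
  expect_equal(res$slope, -2)
  expect_equal(res$cor$pearson_r, -1)
  expect_error(burden_metric_regression(b, rep(3, 5)), "constant metric")
  expect_error(burden_metric_regression(rep(1, 5), b), "constant burden")
})

test_that("moderation analysis matches lm/anova and is coding-invariant", {
  set.seed(4)
  n <- 34
  g <- rep(c("AD", "PSP"), each = 17)
  x <- runif(n)
  y <- ifelse(g == "AD", -x, x) + rnorm(n, sd = 0.3)
  res <- moderation_analysis(x, y, g)
  expect_equal(res$df2, 30)

  fit_full <- lm(y ~ x * factor(g))
  fit_red <- lm(y ~ x + factor(g))
  an <- anova(fit_red, fit_full)
  expect_equal(res$f_stat, an$F[2], tolerance = 1e-10)
  expect_equal(res$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)

  # delta r2 equals the squared semipartial correlation of the interaction
  sp2 <- summary(fit_full)$r.squared - summary(fit_red)$r.squared
  expect_equal(res$delta_r2, sp2, tolerance = 1e-12)

  res2 <- moderation_analysis(x, y, ifelse(g == "AD", 1, 0))
  expect_equal(res2$delta_r2, res$delta_r2, tolerance = 1e-12)
  expect_equal(res2$f_stat, res$f_stat, tolerance = 1e-12)

  expect_error(moderation_analysis(x, y, rep("AD", n)), "two groups")
  idx <- c(1, 2, 18, 19)
  expect_error(moderation_analysis(x[idx], y[idx], g[idx]), "at least 6")
})

test_that("gradient maps are per-node OLS slopes excluding the cerebellum", {
  nt <- make_node_table(10, 2, 3, 2, seed = 1)
  n <- nrow(nt)
  burden <- c(0.2, 0.4, 0.6, 0.8)
  metric <- outer(burden, nt$node_id)  # value = node_id * burden
  gm <- nodal_gradient_map(metric, burden, nt)
  keep <- !nt$is_cerebellar
  expect_equal(unname(gm$slopes), nt$node_id[keep], tolerance = 1e-10)
  expect_length(gm$slopes, sum(keep))

  const <- matrix(5, 4, n)
  gm0 <- nodal_gradient_map(const, burden, nt)
  expect_equal(unname(gm0$slopes), rep(0, sum(keep)))
  expect_error(nodal_gradient_map(metric, rep(1, 4), nt), "constant burden")
})

test_that("sign test matches the closed form and exact binomial p-values", {
  all_pos <- sign_test(rep(1, 100))
  expect_equal(all_pos$z, 10)
  expect_lt(all_pos$p_value, 1e-20)

  balanced <- sign_test(c(rep(1, 50), rep(-1, 50)))
  expect_equal(balanced$z, 0)
  expect_equal(balanced$p_value, 1)

  neg592 <- sign_test(rep(-1, 592))
  expect_equal(neg592$z, (0 - 592) / sqrt(592))
  expect_equal(neg592$z, -24.331, tolerance = 1e-3)

  mixed <- sign_test(c(rep(1, 3), rep(-1, 7), 0, 0))
  expect_equal(mixed$n_nonzero, 10)
  expect_equal(mixed$n_zero, 2)
  expect_equal(mixed$p_value, binom.test(3, 10)$p.value)

  expect_error(sign_test(rep(0, 5)), "all slopes are zero")
})

test_that("gradient-tau correlation uses the non-cerebellar node set", {
  nt <- make_node_table(12, 2, 4, 3, seed = 1)
  keep <- !nt$is_cerebellar
  tau_mean <- runif(nrow(nt))
  tau_mean[!keep] <- 0
  gm <- structure(list(slopes = setNames(-tau_mean[keep], nt$node_id[keep]),
                       node_ids = nt$node_id[keep]), class = "gradient_map")
  res <- gradient_tau_correlation(gm, tau_mean, nt)
  expect_equal(res$pearson_r, -1)
  expect_equal(res$n, sum(keep))

  set.seed(5)
  rs <- replicate(200, {
    gm2 <- gm
    gm2$slopes <- sample(gm2$slopes)
    gradient_tau_correlation(gm2, tau_mean, nt)$pearson_r
  })
  expect_lt(abs(mean(rs)), 0.05)
})
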