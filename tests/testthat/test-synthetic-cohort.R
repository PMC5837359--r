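test_that("node table partitions cortex evenly and flags node roles", {
  nt <- make_node_table(100, 4, 20, 10, seed = 1)
  expect_equal(nrow(nt), 130)
  expect_equal(length(unique(nt$community)), 5)
  expect_equal(sum(nt$is_cerebellar), 10)
  expect_equal(sum(nt$is_subcortical), 20)
  expect_false(any(nt$is_subcortical & nt$is_cerebellar))
  expect_equal(nt$node_id, 0:129)

  one_per <- make_node_table(4, 4, 0, 0, seed = 7)
  expect_equal(sort(table(one_per$community)), sort(table(0:3)))

  big <- make_node_table(598, 6, 18, 30, seed = 3)
  cort_sizes <- table(big$community[!big$is_subcortical & !big$is_cerebellar])
  expect_lte(max(cort_sizes) - min(cort_sizes), 1)

  expect_error(make_node_table(-1, 1), "non-negative")
  expect_error(make_node_table(3, 4), "at least")
})

test_that("node centroids occupy disjoint spatial blocks per lobe", {
  nt <- make_node_table(60, 3, 10, 5, seed = 2)
  ranges <- tapply(nt$x, nt$lobe, range)
  lobes <- names(ranges)
  for (i in seq_along(lobes)) {
    for (j in seq_along(lobes)) {
      if (i < j) {
        expect_true(ranges[[i]][2] < ranges[[j]][1] ||
                      ranges[[j]][2] < ranges[[i]][1])
      }
    }
  }
  expect_identical(make_node_table(60, 3, 10, 5, seed = 2), nt)
})

test_that("base network has planted block, hub and cerebellar structure", {
  nt <- make_node_table(60, 3, 10, 5, seed = 1)
  w <- make_base_network(nt, p_in = 0.3, p_out = 0.05, hub_fraction = 0.1,
                         hub_boost = 2, seed = 4)
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
  same <- outer(nt$community, nt$community, "==")
  expect_gt(mean(w[same & upper.tri(w)] > 0), mean(w[!same & upper.tri(w)] > 0))

  # degenerate probabilities give a block-diagonal support
  wb <- make_base_network(nt, p_in = 1, p_out = 0, hub_fraction = 0,
                          hub_boost = 1, seed = 5)
  expect_true(all(wb[!same] == 0))
  expect_true(all(wb[same & upper.tri(wb)] > 0))

  expect_error(make_base_network(nt, p_in = 0.1, p_out = 0.2), "exceed")
})

test_that("hub nodes out-strength non-hubs in every realization", {
  nt <- make_node_table(50, 4, 0, 0, seed = 1)
  for (s in 1:50) {
    w <- make_base_network(nt, p_in = 0.3, p_out = 0.05, hub_fraction = 0.1,
                           hub_boost = 3, seed = s)
    hubs <- attr(w, "hubs") + 1L
    strength <- rowSums(w)
    expect_gt(mean(strength[hubs]), mean(strength[-hubs]))
  }
})

test_that("cerebellar boost concentrates strength in the cerebellar block", {
  nt <- make_node_table(40, 2, 10, 8, seed = 3)
  w0 <- make_base_network(nt, p_in = 0.4, p_out = 0.05, hub_fraction = 0,
                          hub_boost = 1, cerebellar_boost = 1, seed = 9)
  w4 <- make_base_network(nt, p_in = 0.4, p_out = 0.05, hub_fraction = 0,
                          hub_boost = 1, cerebellar_boost = 4, seed = 9)
  cereb <- nt$is_cerebellar
  expect_equal(w4[!cereb, !cereb], w0[!cereb, !cereb])
  expect_equal(w4[cereb, cereb], 4 * w0[cereb, cereb])
})

test_that("tau maps follow the planted disease regimes", {
  nt <- make_node_table(60, 3, 12, 8, seed = 1)
  s <- rowSums(make_base_network(nt, seed = 2))
  noncereb <- !nt$is_cerebellar

  flat <- generate_tau_map(nt, "CTRL", 0.5, s, beta0 = 0.4, beta1 = 0,
                           sigma = 0, seed = 1)
  expect_true(all(flat[noncereb] == 0.4))
  expect_true(all(flat[!noncereb] == 0))

  ad <- generate_tau_map(nt, "AD", 0.8, s, beta0 = 0.2, beta1 = 1,
                         sigma = 0, seed = 1)
  expect_equal(cor(ad[noncereb], s[noncereb]), 1, tolerance = 1e-12)

  psp <- generate_tau_map(nt, "PSP", 1, s, beta0 = 0.3, beta1 = 1,
                          sigma = 0.01, seed = 1)
  gap <- mean(psp[nt$is_subcortical]) -
    mean(psp[noncereb & !nt$is_subcortical])
  expect_equal(gap, 1, tolerance = 3 * 0.01 / sqrt(12))

  expect_error(generate_tau_map(nt, "FTD", 0.5, s), "unknown mode")
  expect_error(generate_tau_map(nt, "AD", 1.5, s), "burden_param")
})

test_that("tau values are floored at zero and cerebellum stays at zero", {
  nt <- make_node_table(30, 2, 5, 5, seed = 1)
  s <- rowSums(make_base_network(nt, seed = 2))
  tau <- generate_tau_map(nt, "CTRL", 0, s, beta0 = 0.01, beta1 = 0,
                          sigma = 1, seed = 3)
  expect_true(all(tau >= 0))
  expect_true(all(tau[nt$is_cerebellar] == 0))
})

test_that("network modulation follows the planted edge rules", {
  nt <- make_node_table(30, 2, 6, 4, seed = 1)
  w <- make_base_network(nt, p_in = 0.5, p_out = 0.1, hub_fraction = 0,
                         hub_boost = 1, seed = 2)
  tau1 <- rep(1, nrow(nt))

  expect_equal(modulate_subject_network(w, nt, "AD", 1, tau1, gamma = 0),
               w, ignore_attr = TRUE)
  halved <- modulate_subject_network(w, nt, "AD", 1, tau1, gamma = 0.5)
  expect_equal(halved, w / 2, ignore_attr = TRUE)

  psp <- modulate_subject_network(w, nt, "PSP", 1, tau1, gamma = 0.2)
  cort <- !nt$is_subcortical & !nt$is_cerebellar
  sub <- nt$is_subcortical
  cc <- upper.tri(w) & outer(cort, cort, "&") & w > 0
  cs <- upper.tri(w) & outer(cort, sub) & w > 0
  ratio_new <- mean(psp[cc]) / mean(psp[cs])
  ratio_old <- mean(w[cc]) / mean(w[cs])
  expect_equal(ratio_new / ratio_old, 1.2 / 0.8, tolerance = 1e-10)

  expect_equal(psp, t(psp), ignore_attr = TRUE)
  expect_true(all(diag(psp) == 0))
  expect_error(modulate_subject_network(w, nt, "AD", 1, tau1 * 3, gamma = 0.5),
               "must be < 1")
})

test_that("time series sampling is deterministic with planted covariance", {
  nt <- make_node_table(16, 2, 0, 4, seed = 1)
  w <- make_base_network(nt, p_in = 0.6, p_out = 0.1, hub_fraction = 0,
                         hub_boost = 1, seed = 2)
  x1 <- sample_timeseries(w, 100, load = 0.9, seed = 11)
  x2 <- sample_timeseries(w, 100, load = 0.9, seed = 11)
  expect_identical(x1, x2)
  expect_equal(dim(x1), c(20, 100))

  expect_error(sample_timeseries(w, 1), "t_points")
  wasym <- w
  wasym[1, 2] <- wasym[1, 2] + 1
  expect_error(sample_timeseries(wasym, 50), "symmetric")
})

test_that("weak coupling gives near-identity sample correlations", {
  nt <- make_node_table(20, 2, 0, 0, seed = 1)
  w <- make_base_network(nt, p_in = 0.5, p_out = 0.2, hub_fraction = 0,
                         hub_boost = 1, seed = 2)
  x <- sample_timeseries(w, 4000, load = 0.01, seed = 3)
  r <- cor(t(x))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.03)
})

test_that("block-diagonal coupling leaves between-block correlations null", {
  nt <- make_node_table(20, 2, 0, 0, seed = 1)
  w <- make_base_network(nt, p_in = 1, p_out = 0, hub_fraction = 0,
                         hub_boost = 1, seed = 2)
  t_points <- 5000
  x <- sample_timeseries(w, t_points, load = 0.9, seed = 3)
  r <- cor(t(x))
  between <- outer(nt$community, nt$community, "!=")
  expect_lt(mean(abs(r[between])), 3 / sqrt(t_points))
})

test_that("sampling covariances are positive definite for modulated networks", {
  cfg <- small_cohort_config(seed = 5)
  nt <- make_node_table(cfg$n_cortical, cfg$n_communities, cfg$n_subcortical,
                        cfg$n_cerebellar, seed = cfg$seed)
  w <- make_base_network(nt, cfg$p_in, cfg$p_out, cfg$hub_fraction,
                         cfg$hub_boost, cfg$cerebellar_boost, seed = 6)
  s <- rowSums(w)
  for (mode in c("AD", "PSP", "CTRL")) {
    for (b in c(0.1, 0.5, 1)) {
      tau <- generate_tau_map(nt, mode, b, s, seed = 7)
      wm <- modulate_subject_network(w, nt, mode, b, tau, gamma = cfg$gamma)
      sigma <- cfg$load * wm / max(rowSums(wm)) + diag(nrow(wm))
      expect_no_error(chol(sigma))
    }
  }
})

test_that("cohort generation matches configured sizes and regenerates bit-identically", {
  cfg <- cohort_config(seed = 42)
  bundle <- generate_cohort(cfg)
  expect_equal(nrow(bundle$subjects), 46)
  expect_equal(as.vector(table(bundle$subjects$group)[c("AD", "PSP", "CTRL")]),
               c(17, 17, 12))
  expect_length(bundle$timeseries, 46)
  expect_true(all(vapply(bundle$timeseries, function(m) {
    identical(dim(m), c(130L, 250L))
  }, logical(1))))
  expect_identical(generate_cohort(cfg), bundle)

  expect_error(generate_cohort(cohort_config(group_sizes = c(AD = 0, PSP = 1,
                                                             CTRL = 1))),
               "group sizes")
})

test_that("burden parameters respect the per-group severity intervals", {
  bundle <- generate_cohort(small_cohort_config(seed = 8))
  b <- bundle$subjects$burden_param
  g <- bundle$subjects$group
  expect_true(all(b[g == "CTRL"] >= 0 & b[g == "CTRL"] <= 0.1))
  expect_true(all(b[g != "CTRL"] >= 0.1 & b[g != "CTRL"] <= 1))
})

test_that("stronger tau-strength coupling raises the planted tau-strength correlation", {
  nt <- make_node_table(60, 3, 12, 8, seed = 1)
  s <- rowSums(make_base_network(nt, seed = 2))
  noncereb <- !nt$is_cerebellar
  mean_cor <- vapply(c(0.1, 0.4, 1.2), function(b1) {
    mean(vapply(1:12, function(k) {
      tau <- generate_tau_map(nt, "AD", 0.8, s, beta0 = 0.3, beta1 = b1,
                              sigma = 0.15, seed = k)
      cor(tau[noncereb], s[noncereb])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cor) > 0))
})
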