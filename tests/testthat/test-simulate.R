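change_type_names_for_test <- function() {
  c("character", "character_character", "character_object", "temporal",
    "space_large", "space_small", "cause", "goal", "scene")
}

test_that("change-table generation respects degenerate and moment properties", {
  cfg0 <- sim_config(seed = 3, n_bins = 50, change_probs = rep(0, 9))
  expect_true(all(simulate_change_table(cfg0)$n_changes == 0L))

  cfg1 <- sim_config(seed = 3, n_bins = 50, change_probs = rep(1, 9))
  expect_true(all(simulate_change_table(cfg1)$n_changes == 9L))

  # mean count of i.i.d. Bernoulli flags: 9 * 0.1 = 0.9, SE = sqrt(9 p (1-p) / n)
  cfg <- sim_config(seed = 11, n_bins = 900, change_probs = rep(0.1, 9))
  tab <- simulate_change_table(cfg)
  se <- sqrt(9 * 0.1 * 0.9 / 900)
  expect_lt(abs(mean(tab$n_changes) - 0.9), 3 * se)
  expect_identical(tab$n_changes, as.integer(rowSums(tab[, change_type_names_for_test()])))
  expect_identical(tab$bin, 0:899)

  expect_error(sim_config(change_probs = rep(1.2, 9)), "0, 1")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, n_subjects_per_group = 3, n_bins = 40)
  expect_identical(simulate_change_table(cfg), simulate_change_table(cfg))
  tab <- simulate_change_table(cfg)
  expect_identical(simulate_responses(tab, cfg), simulate_responses(tab, cfg))

  spec <- source_sim_spec(grid_shape = c(4, 4, 4), n_planted = 5)
  s1 <- simulate_power_dataset(spec, 4, seed = 9)
  s2 <- simulate_power_dataset(spec, 4, seed = 9)
  expect_identical(s1$groups$group1$bi, s2$groups$group1$bi)
  expect_identical(s1$groups$group2$nbi, s2$groups$group2$nbi)

  lf <- simulate_leadfield(12, 4, seed = 2)
  sp <- sensor_sim_spec(lf, n_segments = 3, sampling_rate = 100)
  expect_identical(
    unclass(simulate_sensor_segments(sp, seed = 4))[],
    unclass(simulate_sensor_segments(sp, seed = 4))[]
  )
})

test_that("response model matches its closed-form moments", {
  # with beta_count = 0 the marginal response rate is E[plogis(beta0 + u)]
  cfg <- sim_config(
    seed = 21, n_subjects_per_group = 60, n_bins = 400,
    beta_count = 0, beta_group_interaction = 0
  )
  tab <- simulate_change_table(cfg)
  resp <- simulate_responses(tab, cfg)
  target <- stats::integrate(
    function(u) plogis(-3.26 + u) * stats::dnorm(u, 0, 0.5), -Inf, Inf
  )$value
  rates <- tapply(resp$response, resp$subject_id, mean)
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - target), 3 * se)

  # zero random-intercept SD: identical per-subject response probabilities,
  # so per-(bin-count) empirical rates match the logistic curve
  cfg2 <- sim_config(
    seed = 22, n_subjects_per_group = 80, n_bins = 300,
    random_intercept_sd = 0, beta_group_interaction = 0
  )
  tab2 <- simulate_change_table(cfg2)
  resp2 <- simulate_responses(tab2, cfg2)
  agg <- tapply(resp2$response, resp2$n_changes, mean)
  truth <- plogis(-3.26 + 0.30 * as.numeric(names(agg)))
  big <- table(resp2$n_changes) > 5000
  expect_true(all(abs(agg[big] - truth[big]) <
                    3 * sqrt(truth[big] * (1 - truth[big]) / table(resp2$n_changes)[big])))

  # strong count slope: response rate monotone increasing in n_changes
  cfg3 <- sim_config(
    seed = 23, n_subjects_per_group = 40, n_bins = 500,
    beta_count = 1.5, beta_group_interaction = 0
  )
  resp3 <- simulate_responses(simulate_change_table(cfg3), cfg3)
  agg3 <- tapply(resp3$response, pmin(resp3$n_changes, 3), mean)
  expect_true(all(diff(agg3) > 0))
})

test_that("response times fall inside their bin", {
  cfg <- sim_config(seed = 31, n_subjects_per_group = 5, n_bins = 100)
  resp <- simulate_responses(simulate_change_table(cfg), cfg)
  hits <- resp[resp$response == 1L, ]
  expect_true(all(hits$time >= hits$bin * 2 & hits$time < (hits$bin + 1) * 2))
  streams <- response_streams(resp)
  expect_true(all(tapply(streams$time, streams$subject_id,
                         function(x) !is.unsorted(x, strictly = TRUE))))
})

test_that("planted power effects have the constructed structure", {
  spec <- source_sim_spec(effect_delta = 0)
  sim <- simulate_power_dataset(spec, 20, seed = 41)
  d <- sim$groups$group1$bi - sim$groups$group1$nbi
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)

  spec2 <- source_sim_spec(effect_delta = 1.5, group_scale = 0.5, n_planted = 20)
  sim2 <- simulate_power_dataset(spec2, 30, seed = 42)
  expect_length(sim2$groups$group2$planted, 10)
  expect_true(all(sim2$groups$group2$planted %in% sim2$groups$group1$planted))
  # planted-vs-outside contrast of the BI - NBI difference is about delta
  d2 <- sim2$groups$group1$bi - sim2$groups$group1$nbi
  inside <- colMeans(d2)[sim2$groups$group1$planted]
  outside <- colMeans(d2)[-sim2$groups$group1$planted]
  gap_se <- sqrt(stats::var(inside) / length(inside) + stats::var(outside) / length(outside))
  expect_lt(abs((mean(inside) - mean(outside)) - 1.5), 3 * gap_se)

  # the default planted region is connected on the lattice
  adj <- build_adjacency(sim2$grid)
  comps <- flood_fill_components(sim2$groups$group1$planted, adj$neighbors)
  expect_length(comps, 1)
})

test_that("sensor segments have the stated geometry", {
  lf <- simulate_leadfield(16, 6, seed = 7)
  sp <- sensor_sim_spec(lf, active_voxel = 3, noise_sd = 0, n_segments = 4)
  segs <- simulate_sensor_segments(sp, seed = 8)
  expect_identical(dim(segs), c(4L, 16L, 600L)) # 2 s at 300 Hz

  # noiseless: every sample lies in the active voxel's 3-dim leadfield span
  L <- lf[, , 3]
  proj <- L %*% solve(crossprod(L), t(L))
  x <- segs[2, , ]
  expect_lt(max(abs(x - proj %*% x)), 1e-10)

  # amplitude zero: pure noise at the requested SD
  sp0 <- sensor_sim_spec(lf, amplitude = 0, noise_sd = 0.5, n_segments = 6)
  segs0 <- simulate_sensor_segments(sp0, seed = 9)
  expect_lt(abs(stats::sd(segs0) - 0.5), 0.02)

  expect_error(
    sensor_sim_spec(lf, source_band = c(100, 160), sampling_rate = 300),
    "Nyquist"
  )
})
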