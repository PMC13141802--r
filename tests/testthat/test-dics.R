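test_that("band CSD is Hermitian, PSD and has the expected structure", {
  lf <- simulate_leadfield(8, 3, seed = 1)
  sp <- sensor_sim_spec(lf, active_voxel = 2, noise_sd = 0.2, n_segments = 12)
  segs <- simulate_sensor_segments(sp, seed = 2)
  csd <- compute_band_csd(segs, band_spec("alpha"))

  expect_equal(csd$values, Conj(t(csd$values)))
  ev <- eigen(csd$values, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(Re(ev) > -1e-12))
  expect_true(all(Re(diag(csd$values)) >= 0))
  # 2-s segments at 300 Hz: alpha 8-12 Hz covers 9 bins at 0.5 Hz spacing
  expect_length(csd$freqs, 9)

  # two identical channels: rank-1 CSD with equal entries
  set.seed(3)
  one <- matrix(rnorm(2 * 300), 2, 300)
  one[2, ] <- one[1, ]
  seg2 <- array(0, dim = c(2, 2, 300))
  seg2[1, , ] <- one
  seg2[2, , ] <- one
  csd2 <- compute_band_csd(seg2, band_spec("alpha"), sampling_rate = 150)
  expect_lt(max(abs(csd2$values - csd2$values[1, 1])), 1e-12)

  expect_error(
    compute_band_csd(segs, band_spec("x", lo = 10.1, hi = 10.2)),
    "No FFT bin"
  )
})

test_that("white-noise off-diagonal CSD shrinks as 1/sqrt(n_segments)", {
  offdiag_mean <- function(n_seg, seed) {
    set.seed(seed)
    segs <- array(rnorm(n_seg * 6 * 200), dim = c(n_seg, 6, 200))
    csd <- compute_band_csd(segs, band_spec("alpha"), sampling_rate = 100)
    m <- abs(csd$values)
    mean(m[upper.tri(m)])
  }
  small <- mean(vapply(1:6, function(s) offdiag_mean(10, s), numeric(1)))
  large <- mean(vapply(1:6, function(s) offdiag_mean(160, s + 50), numeric(1)))
  # expected ratio 4, allow generous Monte-Carlo slack
  expect_gt(small / large, 2.4)
  expect_lt(small / large, 6.5)
})

test_that("spatial filters satisfy unit gain and regularization monotonicity", {
  lf <- simulate_leadfield(20, 10, seed = 5)
  sp <- sensor_sim_spec(lf, active_voxel = 4, noise_sd = 0.3, n_segments = 25)
  segs <- simulate_sensor_segments(sp, seed = 6)
  csd <- compute_band_csd(segs, band_spec("alpha"))

  fl <- compute_dics_filters(csd, lf, lambda = 0.05)
  for (v in c(1, 4, 10)) {
    expect_lt(max(abs(fl$filters[, , v] %*% lf[, , v] - diag(3))), 1e-8)
  }

  # lambda = 0 on a well-conditioned CSD equals the unregularized filter
  C <- Re(csd$values)
  Cinv <- solve(C)
  L <- lf[, , 4]
  manual <- solve(t(L) %*% Cinv %*% L, t(L) %*% Cinv)
  fl0 <- compute_dics_filters(csd, lf, lambda = 0)
  expect_equal(fl0$filters[, , 4], manual, tolerance = 1e-10)

  # increasing lambda shrinks the filter norm monotonically
  norms <- vapply(c(0, 0.05, 0.2, 1, 5), function(lam) {
    f <- compute_dics_filters(csd, lf, lambda = lam)
    sqrt(sum(f$filters[, , 4]^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 1e-12))
})

test_that("power projection is linear, non-negative and localizes a source", {
  lf <- simulate_leadfield(30, 27, seed = 7)
  sp <- sensor_sim_spec(lf, active_voxel = 13, noise_sd = 0, n_segments = 20)
  segs <- simulate_sensor_segments(sp, seed = 8)
  csd <- compute_band_csd(segs, band_spec("alpha"))
  fl <- compute_dics_filters(csd, lf)

  pm <- project_source_power(fl, csd)
  expect_true(all(pm$power >= 0))
  expect_equal(pm$voxel_id[which.max(pm$power)], 13)

  # zero CSD -> zero power; scaling the CSD scales power linearly
  zero <- csd
  zero$values <- csd$values * 0
  expect_true(all(project_source_power(fl, zero)$power == 0))
  scaled <- csd
  scaled$values <- csd$values * 3.7
  expect_equal(project_source_power(fl, scaled)$power, pm$power * 3.7, tolerance = 1e-9)

  # trace summary dominates the eigenvalue summary
  tr <- project_source_power(fl, csd, summary = "trace")
  expect_true(all(tr$power >= pm$power - 1e-12))
})

test_that("power maps are invariant under consistent sensor reordering", {
  lf <- simulate_leadfield(15, 8, seed = 9)
  sp <- sensor_sim_spec(lf, active_voxel = 5, noise_sd = 0.2, n_segments = 15)
  segs <- simulate_sensor_segments(sp, seed = 10)
  csd <- compute_band_csd(segs, band_spec("beta"))
  pm <- project_source_power(compute_dics_filters(csd, lf), csd)

  set.seed(11)
  perm <- sample(15)
  segs_p <- segs[, perm, , drop = FALSE]
  attr(segs_p, "sampling_rate") <- attr(segs, "sampling_rate")
  csd_p <- compute_band_csd(segs_p, band_spec("beta"))
  pm_p <- project_source_power(compute_dics_filters(csd_p, lf[perm, , ]), csd_p)
  expect_equal(pm_p$power, pm$power, tolerance = 1e-8)
})

test_that("a common filter applied to split conditions reproduces the appended CSD power", {
  # appending BI and NBI segments and filtering each condition with the
  # common filter is the common-filter contract: the two power maps must come
  # from the same filter object
  lf <- simulate_leadfield(12, 5, seed = 12)
  sp <- sensor_sim_spec(lf, active_voxel = 2, noise_sd = 0.3, n_segments = 10)
  bi <- simulate_sensor_segments(sp, seed = 13)
  nbi <- simulate_sensor_segments(sp, seed = 14)
  appended <- array(0, dim = c(20, 12, 600))
  appended[1:10, , ] <- unclass(bi)[, , ]
  appended[11:20, , ] <- unclass(nbi)[, , ]
  csd_common <- compute_band_csd(appended, band_spec("alpha"), sampling_rate = 300)
  fl <- compute_dics_filters(csd_common, lf)
  p_bi <- project_source_power(fl, compute_band_csd(unclass(bi), band_spec("alpha"), 300))
  p_nbi <- project_source_power(fl, compute_band_csd(unclass(nbi), band_spec("alpha"), 300))
  p_app <- project_source_power(fl, csd_common)
  # the appended CSD is the segment-count-weighted mean of the condition CSDs
  expect_equal(
    compute_band_csd(appended, band_spec("alpha"), 300)$values,
    (compute_band_csd(unclass(bi), band_spec("alpha"), 300)$values +
       compute_band_csd(unclass(nbi), band_spec("alpha"), 300)$values) / 2,
    tolerance = 1e-10
  )
  expect_true(all(is.finite(c(p_bi$power, p_nbi$power, p_app$power))))
})
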