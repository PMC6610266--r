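test_that("curve extraction takes lobar means (hand-checked toy grid)", {
  # 2-region toy mask on a 3x3x1 grid with printed values
  labels <- array(0L, c(3, 3, 2))
  labels[1:2, 1, 1] <- 1L   # region RUL: two voxels
  labels[3, 3, 1] <- 2L     # region RML: one voxel
  labels[1, 1, 2] <- 3L; labels[2, 1, 2] <- 4L; labels[3, 1, 2] <- 5L
  m <- lobar_masks(labels, c(1, 1, 1))
  sched <- acq_schedule(c(0, 2.5), pulses_per_volume = 1L)
  v1 <- array(0, c(3, 3, 2)); v2 <- array(0, c(3, 3, 2))
  v1[1, 1, 1] <- 2; v1[2, 1, 1] <- 4; v1[3, 3, 1] <- 7
  v2[1, 1, 1] <- 1; v2[2, 1, 1] <- 3; v2[3, 3, 1] <- 5
  ts <- hpx_timeseries(list(voxel_grid(v1, c(1, 1, 1), "hpx_signal"),
                            voxel_grid(v2, c(1, 1, 1), "hpx_signal")), sched)
  curves <- extract_signal_curves(ts, m)
  expect_equal(curves$RUL$values, c((2 + 4) / 2, (1 + 3) / 2))
  expect_equal(curves$RML$values, c(7, 5))   # single-voxel region = its course
})

test_that("uniform volumes give constant curves across lobes", {
  sp <- tiny_spec()
  m <- generate_lobe_masks(sp)
  sched <- acq_schedule(c(0, 2.5, 5))
  vols <- lapply(c(3, 2, 1), function(v) uniform_vol(m, v))
  curves <- extract_signal_curves(hpx_timeseries(vols, sched), m)
  for (cu in curves) expect_equal(cu$values, c(3, 2, 1))
})

test_that("identifiability diagnostic separates schedules", {
  # two volumes: fewer equations than unknowns
  two <- acq_schedule(c(0, 2.5))
  expect_false(check_identifiability(two)$identifiable)
  # uniform spacing at constant pulse count: model collapses to A r^(k-1)
  unif <- acq_schedule(seq(0, by = 2.5, length.out = 8))
  ci_u <- check_identifiability(unif)
  expect_false(ci_u$identifiable)
  expect_gt(ci_u$condition_number, 1e6)
  # the collapse is real: distinct (alpha, T1) pairs on the same combined
  # rate produce numerically identical curves
  a1 <- 10; T1a <- 20
  rate <- 8 * log(1 / cos(a1 * pi / 180)) + 2.5 / T1a
  a2 <- 8
  T1b <- 2.5 / (rate - 8 * log(1 / cos(a2 * pi / 180)))
  c1 <- hpx_signal_model(1, a1, T1a, unif)
  c2 <- hpx_signal_model(sin(a1 * pi / 180) / sin(a2 * pi / 180), a2, T1b, unif)
  expect_equal(c1, c2, tolerance = 1e-12)
  # non-uniform times break the collapse
  nonu <- acq_schedule(c(0, 2.5, 7.5, 10))
  ci_n <- check_identifiability(nonu)
  expect_true(ci_n$identifiable)
  expect_lt(ci_n$condition_number, 1e4)
  expect_true(check_identifiability(identifiable_schedule())$identifiable)
})

test_that("noiseless fits recover parameters exactly (round trip)", {
  cases <- list(c(1, 10, 20), c(0.5, 6, 35), c(2, 15, 12))
  sched <- identifiable_schedule()
  for (p in cases) {
    y <- hpx_signal_model(p[1], p[2], p[3], sched)
    f <- fit_decay_model(signal_curve(y, sched))
    expect_lt(abs(f$S0 - p[1]) / p[1], 1e-6)
    expect_lt(abs(f$alpha - p[2]) / p[2], 1e-6)
    expect_lt(abs(f$T1 - p[3]) / p[3], 1e-6)
    expect_gt(f$r_squared, 1 - 1e-12)
    expect_true(f$identifiable)
  }
})

test_that("three non-uniform time points suffice for the three unknowns", {
  sched3 <- acq_schedule(c(0, 2.5, 7.5))
  y <- hpx_signal_model(0.7, 12, 25, sched3)
  f <- fit_decay_model(signal_curve(y, sched3))
  expect_lt(abs(f$S0 - 0.7) / 0.7, 1e-6)
  expect_lt(abs(f$alpha - 12) / 12, 1e-6)
  expect_lt(abs(f$T1 - 25) / 25, 1e-6)
})

test_that("non-identifiable fits still recover the combined decay rate", {
  unif <- acq_schedule(seq(0, by = 2.5, length.out = 8))
  y <- hpx_signal_model(1, 10, 20, unif)
  f <- fit_decay_model(signal_curve(y, unif))
  expect_false(f$identifiable)
  # frozen: 8 log(sec 10 deg) + 2.5 / 20
  expect_equal(f$decay_rate, 0.24747065172788611, tolerance = 1e-6)
})

test_that("r_squared is invariant under positive rescaling of the curve", {
  sched <- identifiable_schedule()
  y <- hpx_signal_model(1, 10, 20, sched)
  set.seed(11)
  yn <- y + rnorm(8, 0, y[1] / 30)
  f1 <- fit_decay_model(signal_curve(yn, sched))
  f2 <- fit_decay_model(signal_curve(17.3 * yn, sched))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-9)
  expect_equal(f2$S0 / f1$S0, 17.3, tolerance = 1e-6)
})

test_that("fit preconditions are enforced", {
  sched <- identifiable_schedule()
  expect_error(fit_decay_model(signal_curve(rep(0, 8), sched)), "all-zero")
  y <- hpx_signal_model(1, 10, 20, sched)
  expect_error(fit_decay_model(signal_curve(-y, sched)), "positive")
  expect_error(fit_decay_model(signal_curve(c(1, 0.5), acq_schedule(c(0, 2.5)))),
               "at least 3")
})

test_that("noiseless correction inverts the simulation up to one global scale", {
  sp <- tiny_spec(coil_ap_ratio = 1, noise_sd = 0)
  m <- generate_lobe_masks(sp)
  vent <- generate_ventilation_map(sp, m)
  amap <- generate_coil_alpha_map(sp)
  ts <- simulate_hpx_timeseries(vent, amap, sp$T1_seconds,
                                identifiable_schedule(), noise_sd = 0)
  fits <- fit_regional_decay(ts, m)
  corr <- correct_timeseries(ts, fits, m)
  scale <- sin(sp$nominal_alpha * pi / 180)
  inlung <- m$labels > 0L
  expect_lt(max(abs(corr$values[inlung] / scale - vent$values[inlung])), 1e-8)
  # corrected voxel time courses are constant: CV below 1e-6
  f <- fits$RUL
  k <- seq_len(ts$schedule$n_volumes)
  fac <- cos(f$alpha * pi / 180)^(8 * (k - 1)) *
    exp(-ts$schedule$volume_times / f$T1)
  vox <- which(m$labels == 1L)[1]
  course <- sapply(k, function(kk) ts$volumes[[kk]]$values[vox] / fac[kk])
  expect_lt(sd(course) / mean(course), 1e-6)
})

test_that("per-bin fits remove a factor-2 coil gradient from uniform lungs", {
  sp <- tiny_spec(coil_ap_ratio = 2, noise_sd = 0,
                  ventilation_defect_fraction_per_lobe = rep(0, 5))
  m <- generate_lobe_masks(sp)
  vent <- uniform_vol(m, 0)
  vent$values[m$labels > 0L] <- 0.8
  vent$role <- "ventilation_fraction"
  amap <- generate_coil_alpha_map(sp)
  ts <- simulate_hpx_timeseries(vent, amap, sp$T1_seconds,
                                identifiable_schedule(), noise_sd = 0)
  bins <- intensity_bin_masks(ts, m, n_bins = 10)
  fits <- fit_regional_decay(ts, bins)
  corr <- correct_timeseries(ts, fits, bins)
  ys <- slice.index(m$labels, 2)
  lung <- m$labels > 0L
  yr <- range(ys[lung])
  ant <- lung & ys >= yr[2] - 2
  post <- lung & ys <= yr[1] + 2
  before <- mean(ts$volumes[[1]]$values[ant]) / mean(ts$volumes[[1]]$values[post])
  after <- mean(corr$values[ant]) / mean(corr$values[post])
  expect_gt(before, 1.15)           # the gradient is present pre-correction
  expect_lt(abs(after - 1), 0.02)   # and removed by per-bin correction
})

test_that("identity decay reduces correction to the mean of the volumes", {
  m <- slab_masks()
  sched <- acq_schedule(c(0, 0.5, 1), pulses_per_volume = 1L)
  vols <- lapply(c(1, 1.2, 0.8), function(v) uniform_vol(m, v))
  ts <- hpx_timeseries(vols, sched)
  idsched <- identifiable_schedule()
  template <- fit_decay_model(signal_curve(hpx_signal_model(1, 10, 20, idsched),
                                           idsched))
  fits <- lapply(LOBE_NAMES, function(l) {
    f <- template
    f$alpha <- 0.2; f$T1 <- 199; f$identifiable <- TRUE
    f
  })
  names(fits) <- LOBE_NAMES
  corr <- correct_timeseries(ts, fits, m, alpha_ref = 0.2)
  expect_equal(mean(corr$values[m$labels > 0L]), mean(c(1, 1.2, 0.8)),
               tolerance = 5e-3)
})

test_that("parameter recovery at SNR 50 is nearly unbiased", {
  sched <- identifiable_schedule()
  y <- hpx_signal_model(1, 10, 20, sched)
  set.seed(99)
  est <- vapply(1:200, function(i) {
    f <- fit_decay_model(signal_curve(y + rnorm(8, 0, y[1] / 50), sched))
    c(f$alpha, f$T1)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 10), 0.5)
  expect_lt(abs(mean(est[2, ]) - 20) / 20, 0.10)
})
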