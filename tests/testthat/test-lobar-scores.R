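test_that("emphysema percentage matches hand counts on toy volumes", {
  m <- slab_masks(3, 3, 10, spacing = c(1, 1, 1))
  hu <- uniform_vol(m, -800, role = "HU")
  expect_equal(unname(emphysema_pct(hu, m)[1:5]), rep(0, 5))
  hu$values[] <- -1000
  expect_equal(unname(emphysema_pct(hu, m)[1:5]), rep(100, 5))
  # 2 of 18 voxels of RUL at -960 HU -> 11.11%; 2 of 9 in one slice -> 22.22%
  hu$values[] <- -800
  hu$values[1:2, 1, 1] <- -960
  got <- emphysema_pct(hu, m)
  expect_equal(got[["RUL"]], 100 * 2 / 18, tolerance = 1e-12)
  # threshold is strict: voxels exactly at the cut do not count
  hu$values[1:2, 1, 1] <- -950
  expect_equal(emphysema_pct(hu, m)[["RUL"]], 0)
})

test_that("emphysema percentage is non-decreasing in the threshold", {
  sp <- tiny_spec()
  m <- generate_lobe_masks(sp)
  ct <- generate_ct_volume(sp, m)
  thresholds <- c(-1000, -975, -950, -925, -900)
  wl <- vapply(thresholds,
               function(t) emphysema_pct(ct, m, t)[["whole_lung"]], numeric(1))
  expect_true(all(diff(wl) >= 0))
})

test_that("relative shares: symmetry, concentration, exact conservation", {
  m <- slab_masks()   # five equal-volume lobes
  u <- uniform_vol(m, 2)
  rel <- relative_ventilation_pct(u, m)
  expect_equal(unname(rel), rep(20, 5), tolerance = 1e-12)
  # all signal in RUL
  s <- uniform_vol(m, 0)
  s$values[m$labels == 1L] <- 3
  rel1 <- relative_ventilation_pct(s, m)
  expect_equal(unname(rel1), c(100, 0, 0, 0, 0))
  # any input sums to 100 within 1e-9
  set.seed(4)
  for (i in 1:5) {
    r <- uniform_vol(m, 0)
    r$values[] <- runif(length(r$values))
    expect_lt(abs(sum(relative_ventilation_pct(r, m)) - 100), 1e-9)
  }
  expect_error(relative_ventilation_pct(uniform_vol(m, 0), m), "zero")
  neg <- uniform_vol(m, -1)
  expect_error(relative_ventilation_pct(neg, m), "negative")
})

test_that("absolute defect score: trivial cases and threshold semantics", {
  m <- slab_masks()
  u <- uniform_vol(m, 1)
  expect_equal(unname(absolute_ventilation_defect_pct(u, m)[1:5]), rep(0, 5))
  # one lobe fully void -> 100% there, 0 elsewhere
  s <- uniform_vol(m, 1)
  s$values[m$labels == 3L] <- 0
  d <- absolute_ventilation_defect_pct(s, m)
  expect_equal(d[["RLL"]], 100)
  expect_equal(unname(d[c("RUL", "RML", "LUL", "LLL")]), rep(0, 4))
  expect_error(absolute_ventilation_defect_pct(uniform_vol(m, 0), m), "all-zero")
  # non-decreasing in the threshold fraction
  sp <- tiny_spec()
  mm <- generate_lobe_masks(sp)
  v <- generate_ventilation_map(sp, mm)
  fr <- c(0.02, 0.05, 0.10, 0.20)
  wl <- vapply(fr, function(f)
    absolute_ventilation_defect_pct(v, mm, f)[["whole_lung"]], numeric(1))
  expect_true(all(diff(wl) >= 0))
})

test_that("phantom defect burden is recovered by the defect score", {
  sp <- tiny_spec(ventilation_defect_fraction_per_lobe = c(0, 0, 0, 0, 0.25))
  m <- generate_lobe_masks(sp)
  v <- generate_ventilation_map(sp, m)
  d <- absolute_ventilation_defect_pct(v, m)
  expect_lt(abs(d[["LLL"]] - 25), 5)
})

test_that("scoring matches brute-force voxel loops to 1e-12 on small grids", {
  sp <- phantom_spec(grid_shape = c(16L, 16L, 14L))
  m <- generate_lobe_masks(sp)
  ct <- generate_ct_volume(sp, m)
  expect_equal(unname(emphysema_pct(ct, m)), brute_emphysema(ct, m),
               tolerance = 1e-12)
  v <- generate_ventilation_map(sp, m)
  expect_equal(unname(absolute_ventilation_defect_pct(v, m)),
               brute_defect(v, m), tolerance = 1e-12)
})

test_that("SPECT lobar shares resample masks and recover seeded ratios", {
  m <- slab_masks(16, 16, 20)
  u <- uniform_vol(m, 5, role = "spect_counts")
  expect_equal(unname(spect_lobar_pct(u, m)), rep(20, 5), tolerance = 1e-9)
  # counts only in the left-lung labels
  s <- uniform_vol(m, 0, role = "spect_counts")
  s$values[m$labels %in% c(4L, 5L)] <- 2
  shares <- spect_lobar_pct(s, m)
  expect_equal(shares[["LUL"]] + shares[["LLL"]], 100, tolerance = 1e-9)
  # known lobar activity ratios survive blur + resample + Poisson within 3 pts
  sp <- phantom_spec(spect_pixel = 6)
  mm <- generate_lobe_masks(sp)
  act <- uniform_vol(mm, 0, role = "spect_counts")
  target <- c(30, 20, 20, 15, 15)
  counts <- lobe_voxel_counts(mm)
  for (l in 1:5) act$values[mm$labels == l] <- target[l] / counts[l]
  got <- rowMeans(vapply(1:10, function(s) {
    sp$random_seed <- s
    unname(spect_lobar_pct(spect_degrade(act, sp, stream = 7), mm))
  }, numeric(5)))
  expect_true(all(abs(got - target) < 3))
})

test_that("score table assembles rows and flags missing modalities as NA", {
  sp <- tiny_spec()
  m <- generate_lobe_masks(sp)
  ct <- generate_ct_volume(sp, m)
  v <- generate_ventilation_map(sp, m)
  tab <- lobar_score_table("S01", ct = ct, hpx_corrected = v,
                           spect_v = NULL, spect_q = NULL, masks = m)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$lobe, c(LOBE_NAMES, "whole_lung"))
  expect_true(all(is.na(tab$spect_vent_pct)))
  expect_false(any(is.na(tab$ct_emphysema_pct)))
  lob <- tab[tab$lobe != "whole_lung", ]
  expect_lt(abs(sum(lob$hpx_rel_vent_pct) - 100), 1e-9)
})

test_that("lobes with more seeded disease rank lower in ventilation share", {
  sp <- small_spec(
    emphysema_fraction_per_lobe = c(0.05, 0.05, 0.45, 0.05, 0.30),
    ventilation_defect_fraction_per_lobe = c(0.05, 0.05, 0.45, 0.05, 0.30))
  m <- generate_lobe_masks(sp)
  ct <- generate_ct_volume(sp, m)
  v <- generate_ventilation_map(sp, m)
  e <- emphysema_pct(ct, m)[1:5]
  rel <- relative_ventilation_pct(v, m)
  dd <- absolute_ventilation_defect_pct(v, m)[1:5]
  # volume-share differences confound raw rank checks, so compare the
  # diseased lobes against their own healthy counterparts per lung
  expect_lt(rel[["RLL"]] / lobe_voxel_counts(m)[["RLL"]],
            rel[["RUL"]] / lobe_voxel_counts(m)[["RUL"]])
  expect_gt(dd[["RLL"]], dd[["RUL"]])
  expect_gt(dd[["LLL"]], dd[["LUL"]])
  expect_gt(e[["RLL"]], e[["RUL"]])
})
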