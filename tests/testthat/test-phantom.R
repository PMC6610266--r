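test_that("lobe masks are disjoint, complete, deterministic and nonempty", {
  sp <- small_spec()
  m1 <- generate_lobe_masks(sp)
  m2 <- generate_lobe_masks(sp)
  expect_identical(m1$labels, m2$labels)
  counts <- lobe_voxel_counts(m1)
  expect_true(all(counts >= 50))          # every lobe well populated at 32x32x24
  # labels partition the lungs: right lung = labels 1:3, left = 4:5
  expect_setequal(sort(unique(as.vector(m1$labels))), 0:5)
  # a brute-force pass over the volume agrees with the tabulated counts
  brute <- integer(5)
  for (v in as.vector(m1$labels)) if (v > 0L) brute[v] <- brute[v] + 1L
  expect_identical(unname(counts), brute)
})

test_that("degenerate geometry names the vanishing lobe", {
  sp <- small_spec()
  sp$lobe_geometry_params$right$radii <- c(1e-6, 1e-6, 1e-6)
  expect_error(generate_lobe_masks(sp), "RLL|RUL|RML")
})

test_that("CT volume hits zero, saturated and fractional emphysema targets", {
  sp0 <- small_spec(emphysema_fraction_per_lobe = rep(0, 5))
  m <- generate_lobe_masks(sp0)
  e0 <- emphysema_pct(generate_ct_volume(sp0, m), m)
  expect_true(all(e0[1:5] < 2))           # only the parenchyma tail below -950

  sp1 <- small_spec(emphysema_fraction_per_lobe = c(0, 0, 1, 0, 0))
  e1 <- emphysema_pct(generate_ct_volume(sp1, m), m)
  expect_gt(e1[["RLL"]], 95)

  # fraction 0.29 in RLL: measured score within +/- 3 points over 20 seeds
  scores <- vapply(1:20, function(s) {
    sp <- small_spec(emphysema_fraction_per_lobe = c(0, 0, 0.29, 0, 0),
                     random_seed = s)
    emphysema_pct(generate_ct_volume(sp, m), m)[["RLL"]]
  }, numeric(1))
  expect_true(all(abs(scores - 29) < 3))
})

test_that("CT is reproducible under the spec seed and soft tissue sits above -200 HU", {
  sp <- small_spec(random_seed = 7L)
  m <- generate_lobe_masks(sp)
  expect_identical(generate_ct_volume(sp, m)$values,
                   generate_ct_volume(sp, m)$values)
  ct <- generate_ct_volume(sp, m)
  expect_true(all(ct$values[m$labels == 0L] > -200))
})

test_that("ventilation map honours defect fractions and support", {
  sp <- small_spec(ventilation_defect_fraction_per_lobe = rep(0, 5))
  m <- generate_lobe_masks(sp)
  v0 <- generate_ventilation_map(sp, m)
  expect_true(all(v0$values[m$labels > 0L] >= 0.5))
  expect_true(all(v0$values[m$labels == 0L] == 0))

  sp1 <- small_spec(ventilation_defect_fraction_per_lobe = c(0, 0, 0, 0, 1))
  v1 <- generate_ventilation_map(sp1, m)
  expect_lt(mean(v1$values[m$labels == 5L]), 0.05)

  # defect fraction 0.25 in LLL: voxel share below 5% of the whole-lung
  # reference within +/- 0.05 of the target (brute-force voxel count)
  sp2 <- small_spec(ventilation_defect_fraction_per_lobe = c(0, 0, 0, 0, 0.25))
  v2 <- generate_ventilation_map(sp2, m)
  lungv <- v2$values[m$labels > 0L]
  thr <- 0.05 * quantile(lungv, 0.99, names = FALSE)
  got <- sum(v2$values[m$labels == 5L] < thr) / sum(m$labels == 5L)
  expect_lt(abs(got - 0.25), 0.05)
})

test_that("measured fractions converge to spec fractions as the grid refines", {
  frac_err <- function(shape) {
    sp <- phantom_spec(grid_shape = shape,
                       emphysema_fraction_per_lobe = rep(0.2, 5))
    m <- generate_lobe_masks(sp)
    e <- emphysema_pct(generate_ct_volume(sp, m), m)
    max(abs(e[1:5] - 20))
  }
  coarse <- frac_err(c(20L, 20L, 16L))
  fine <- frac_err(c(40L, 40L, 32L))
  expect_lt(fine, coarse + 0.5)   # refinement does not degrade recovery
  expect_lt(fine, 2.5)
})

test_that("coil flip-angle map realizes the anterior-posterior signal ratio", {
  sp1 <- small_spec(coil_ap_ratio = 1)
  a1 <- generate_coil_alpha_map(sp1)
  expect_true(all(a1$values == sp1$nominal_alpha))

  sp2 <- small_spec(coil_ap_ratio = 2, nominal_alpha = 10)
  a2 <- generate_coil_alpha_map(sp2)
  sr <- sin(max(a2$values) * pi / 180) / sin(min(a2$values) * pi / 180)
  expect_lt(abs(sr - 2), 1e-3)
  # small-angle limit: alpha ratio itself close to 2
  expect_lt(abs(max(a2$values) / min(a2$values) - 2), 0.05)
  # monotone along the posterior-to-anterior (y) axis
  prof <- a2$values[1, , 1]
  expect_true(all(diff(prof) > 0))
  sp_bad <- sp2
  sp_bad$coil_ap_ratio <- 0.5
  expect_error(generate_coil_alpha_map(sp_bad), ">= 1")
})

test_that("SPECT degradation blurs to the stated resolution and conserves counts", {
  sp <- small_spec(spect_pixel = 4)
  m <- generate_lobe_masks(sp)
  v <- generate_ventilation_map(sp, m)

  # zero input -> zero counts
  z <- uniform_vol(m, 0)
  expect_true(all(spect_degrade(z, sp)$values == 0))
  expect_error(spect_degrade(uniform_vol(m, -1), sp), "negative")

  # expected (pre-noise) blur+resample conserves the total within 0.5%
  sigma_vox <- (sp$spect_resolution_fwhm / (2 * sqrt(2 * log(2)))) / 4
  blurred <- xelobe:::gaussian_smooth3d(v$values, sigma_vox)
  res <- resample_volume(voxel_grid(blurred, v$spacing, "spect_counts"),
                         rep(6, 3), conserve_sum = TRUE)
  expect_lt(abs(sum(res$values) - sum(v$values)) / sum(v$values), 0.005)

  # delta impulse -> profile with FWHM = 10 mm within one output pixel
  imp <- array(0, sp$grid_shape)
  imp[16, 16, 12] <- 1
  pre <- spect_degrade(voxel_grid(imp, v$spacing, "spect_counts"), sp,
                       poisson = FALSE)
  prof <- pre$values[, 16, 12]
  half <- max(prof) / 2
  above <- which(prof >= half)
  fwhm_mm <- (max(above) - min(above) + 1) * pre$spacing[1]
  expect_lt(abs(fwhm_mm - sp$spect_resolution_fwhm), 4 + 1e-9)

  # Poisson stage is seeded and reproducible
  expect_identical(spect_degrade(v, sp)$values, spect_degrade(v, sp)$values)
})

test_that("phantom_spec validates its invariants", {
  expect_error(small_spec(emphysema_fraction_per_lobe = rep(1.2, 5)), "\\[0, 1\\]")
  expect_error(small_spec(emphysema_hu_mean = -900), "-950")
  expect_error(small_spec(parenchyma_hu_mean = -960), "-950")
  expect_error(small_spec(coil_ap_ratio = 0.9), ">= 1")
  expect_error(phantom_spec(grid_shape = c(0, 10, 10)), "positive")
})

test_that("cohort generator couples emphysema, defect and spirometry", {
  ch <- generate_phantom_cohort(n_subjects = 8, base_spec = tiny_spec(), seed = 3)
  expect_length(ch$specs, 8)
  emph <- vapply(ch$specs, function(s) mean(s$emphysema_fraction_per_lobe), numeric(1))
  defect <- vapply(ch$specs, function(s)
    mean(s$ventilation_defect_fraction_per_lobe), numeric(1))
  expect_gt(cor(emph, defect), 0.9)
  expect_lt(cor(defect, ch$covariates$fev1_pct_pred), -0.9)
  expect_lt(cor(defect, ch$covariates$fev1_fvc_pct), -0.9)
  # deterministic
  ch2 <- generate_phantom_cohort(n_subjects = 8, base_spec = tiny_spec(), seed = 3)
  expect_identical(ch$covariates, ch2$covariates)
})
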