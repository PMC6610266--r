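#' Digital thorax phantom specification
#'
#' Collects every parameter of the synthetic five-lobe lung phantom: grid
#' geometry, lobar emphysema and ventilation-defect burdens, CT attenuation
#' distributions, the receive-coil flip-angle inhomogeneity, the
#' hyperpolarized-gas acquisition physics, and the SPECT degradation model.
#' The defaults describe a moderately emphysematous subject whose lobar
#' burden pattern is highest in the lower lobes, on a 56 x 56 x 44 grid at
#' 4 mm isotropic spacing (a scaled-down adult thorax).
#'
#' @param grid_shape integer length-3 voxel counts, all positive.
#' @param voxel_spacing numeric length-3 voxel spacing in mm.
#' @param lobe_geometry_params list with per-lung ellipsoid `centre` and
#'   `radii` (fractions of the grid extent) and the oblique-fissure slope
#'   `fissure_slope` (unitless; fissure coordinate is z + slope * y).
#' @param emphysema_fraction_per_lobe five values in \[0, 1\]: target fraction
#'   of each lobe occupied by clustered low-attenuation (emphysema) tissue,
#'   ordered RUL, RML, RLL, LUL, LLL.
#' @param ventilation_defect_fraction_per_lobe five values in \[0, 1\]: target
#'   fraction of each lobe occupied by ventilation defects (signal near zero).
#' @param parenchyma_hu_mean,parenchyma_hu_sd normal parenchyma attenuation
#'   distribution, HU. The mean must sit above the -950 HU emphysema cut.
#' @param emphysema_hu_mean,emphysema_hu_sd emphysematous tissue attenuation
#'   distribution, HU. The mean must sit below -950 HU.
#' @param coil_ap_ratio anterior-to-posterior first-volume signal ratio
#'   produced by the coil profile, >= 1 (default 2: surface-coil receive
#'   profiles commonly double the signal from anterior versus posterior lung).
#' @param nominal_alpha nominal excitation flip angle, degrees.
#' @param T1_seconds longitudinal decay time of the hyperpolarized
#'   magnetization during breath-hold, seconds.
#' @param noise_sd additive Gaussian noise s.d. on simulated gas-MRI images,
#'   arbitrary units. A free parameter of the phantom (in-vivo SNR is not a
#'   fixed property of the method); the default gives first-volume SNR near
#'   50 for a well-ventilated voxel at the default flip angle.
#' @param spect_resolution_fwhm SPECT system resolution, mm FWHM (default 10).
#' @param spect_pixel SPECT reconstruction pixel size, mm (default 4).
#' @param spect_total_counts expected total counts in a SPECT volume.
#' @param random_seed integer seed; identical specs give identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(56L, 56L, 44L),
                         voxel_spacing = c(4, 4, 4),
                         lobe_geometry_params = default_lobe_geometry(),
                         emphysema_fraction_per_lobe =
                           c(RUL = 0.15, RML = 0.18, RLL = 0.29,
                             LUL = 0.18, LLL = 0.25),
                         ventilation_defect_fraction_per_lobe =
                           c(RUL = 0.10, RML = 0.12, RLL = 0.28,
                             LUL = 0.12, LLL = 0.22),
                         parenchyma_hu_mean = -850, parenchyma_hu_sd = 40,
                         emphysema_hu_mean = -980, emphysema_hu_sd = 15,
                         coil_ap_ratio = 2,
                         nominal_alpha = 10,
                         T1_seconds = 20,
                         noise_sd = 0.003,
                         spect_resolution_fwhm = 10,
                         spect_pixel = 4,
                         spect_total_counts = 2e6,
                         random_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L)) {
    stop_("grid_shape must be 3 positive integers")
  }
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0)) {
    stop_("voxel_spacing must be 3 positive numbers (mm)")
  }
  ef <- check_fractions(emphysema_fraction_per_lobe, "emphysema_fraction_per_lobe")
  df <- check_fractions(ventilation_defect_fraction_per_lobe,
                        "ventilation_defect_fraction_per_lobe")
  if (emphysema_hu_mean >= -950) {
    stop_("emphysema_hu_mean must be below -950 HU (got %g)", emphysema_hu_mean)
  }
  if (parenchyma_hu_mean <= -950) {
    stop_("parenchyma_hu_mean must be above -950 HU (got %g)", parenchyma_hu_mean)
  }
  if (!is.numeric(coil_ap_ratio) || coil_ap_ratio < 1) {
    stop_("coil_ap_ratio must be >= 1 (got %g)", coil_ap_ratio)
  }
  if (nominal_alpha <= 0 || nominal_alpha >= 90) {
    stop_("nominal_alpha must be in (0, 90) degrees")
  }
  if (T1_seconds <= 0) stop_("T1_seconds must be positive")
  if (noise_sd < 0) stop_("noise_sd must be nonnegative")
  if (spect_resolution_fwhm <= 0 || spect_pixel <= 0) {
    stop_("SPECT resolution and pixel size must be positive")
  }
  structure(list(
    grid_shape = grid_shape, voxel_spacing = voxel_spacing,
    lobe_geometry_params = lobe_geometry_params,
    emphysema_fraction_per_lobe = ef,
    ventilation_defect_fraction_per_lobe = df,
    parenchyma_hu_mean = parenchyma_hu_mean, parenchyma_hu_sd = parenchyma_hu_sd,
    emphysema_hu_mean = emphysema_hu_mean, emphysema_hu_sd = emphysema_hu_sd,
    coil_ap_ratio = coil_ap_ratio, nominal_alpha = nominal_alpha,
    T1_seconds = T1_seconds, noise_sd = noise_sd,
    spect_resolution_fwhm = spect_resolution_fwhm, spect_pixel = spect_pixel,
    spect_total_counts = spect_total_counts,
    random_seed = as.integer(random_seed)
  ), class = "phantom_spec")
}

check_fractions <- function(x, what) {
  x <- as.numeric(x)
  if (length(x) != 5L || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_("%s must be 5 values in [0, 1]", what)
  }
  stats::setNames(x, LOBE_NAMES)
}

#' Default lung-ellipsoid geometry of the phantom
#'
#' Two half-overlapping ellipsoids (right and left lung) expressed as
#' fractions of the grid extent, split into lobes by oblique planes of
#' constant `z + fissure_slope * y`.
#' @return list of geometry parameters.
#' @export
default_lobe_geometry <- function() {
  list(
    right = list(centre = c(0.30, 0.52, 0.50), radii = c(0.17, 0.30, 0.42)),
    left  = list(centre = c(0.71, 0.52, 0.50), radii = c(0.16, 0.28, 0.40)),
    fissure_slope = 0.35
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec: grid %s @ %s mm, seed %d>\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_spacing, collapse = "x"), x$random_seed))
  cat("  emphysema fractions: ",
      paste(sprintf("%s=%.2f", LOBE_NAMES, x$emphysema_fraction_per_lobe),
            collapse = " "), "\n", sep = "")
  cat("  defect fractions:    ",
      paste(sprintf("%s=%.2f", LOBE_NAMES, x$ventilation_defect_fraction_per_lobe),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

# Fractional voxel-centre coordinate arrays of a grid (0..1 per axis).
frac_coords <- function(shape) {
  fx <- (seq_len(shape[1]) - 0.5) / shape[1]
  fy <- (seq_len(shape[2]) - 0.5) / shape[2]
  fz <- (seq_len(shape[3]) - 0.5) / shape[3]
  list(
    x = array(rep(fx, times = shape[2] * shape[3]), shape),
    y = array(rep(rep(fy, each = shape[1]), times = shape[3]), shape),
    z = array(rep(fz, each = shape[1] * shape[2]), shape)
  )
}

#' Generate the five-lobe mask volume of a phantom subject
#'
#' Builds two ellipsoidal lungs and cuts them into three right and two left
#' lobes along oblique fissure planes. The fissure positions are chosen as
#' quantiles of the oblique coordinate inside each lung so lobe volume shares
#' are stable across grids (right lung 3 lobes at 1/3, 2/3; left lung 2 lobes
#' at 0.45). Entirely deterministic: no random numbers are used.
#'
#' @param spec a [phantom_spec()].
#' @return A [lobar_masks()] object.
#' @export
generate_lobe_masks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  g <- spec$lobe_geometry_params
  co <- frac_coords(shape)
  inside <- function(lung) {
    ((co$x - lung$centre[1]) / lung$radii[1])^2 +
      ((co$y - lung$centre[2]) / lung$radii[2])^2 +
      ((co$z - lung$centre[3]) / lung$radii[3])^2 <= 1
  }
  right <- inside(g$right)
  left <- inside(g$left) & !right
  labels <- array(0L, shape)
  w <- co$z + g$fissure_slope * co$y   # oblique fissure coordinate
  split_lung <- function(mask, cuts, lobe_ids) {
    if (!any(mask)) {
      stop_("lobe %s has zero voxels: degenerate lung geometry",
            LOBE_NAMES[lobe_ids[1]])
    }
    wv <- w[mask]
    qs <- stats::quantile(wv, probs = cuts, names = FALSE, type = 7)
    bin <- findInterval(wv, qs, left.open = TRUE)  # 0..length(cuts)
    labels[mask] <<- lobe_ids[bin + 1L]
  }
  # lowest oblique coordinate = most inferior/posterior = lower lobe
  split_lung(right, c(1 / 3, 2 / 3), c(3L, 2L, 1L))  # RLL, RML, RUL
  split_lung(left, 0.45, c(5L, 4L))                   # LLL, LUL
  counts <- tabulate(labels, nbins = 5L)
  if (any(counts == 0L)) {
    stop_("lobe %s has zero voxels: grid too coarse for the geometry",
          LOBE_NAMES[which(counts == 0L)[1]])
  }
  lobar_masks(labels, spec$voxel_spacing)
}

# Smooth standardized Gaussian random field on the grid (mean 0, sd ~ 1).
smooth_field <- function(shape, sigma_vox, seed) {
  f <- with_seed(seed, array(stats::rnorm(prod(shape)), shape))
  f <- gaussian_smooth3d(f, sigma_vox)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a CT-like attenuation volume with clustered emphysema
#'
#' Inside each lobe, the target fraction of voxels forming spatially
#' coherent clusters is assigned the emphysematous attenuation distribution
#' and the remainder the normal-parenchyma distribution; voxels outside the
#' lungs get soft-tissue attenuation. Clusters are the upper tail of a
#' smooth Gaussian random field thresholded at the per-lobe quantile
#' matching the requested fraction, which makes the low-attenuation regions
#' contiguous blobs (as emphysema appears on CT) while hitting the target
#' voxel fraction exactly.
#'
#' @param spec a [phantom_spec()].
#' @param masks the subject's [lobar_masks()].
#' @return `voxel_grid` with role `"HU"`.
#' @export
generate_ct_volume <- function(spec, masks) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(masks, "lobar_masks"))
  shape <- spec$grid_shape
  if (!identical(dim(masks$labels), shape)) stop_("masks are not on the spec grid")
  field <- smooth_field(shape, sigma_vox = 2, seed = derive_seed(spec$random_seed, 11))
  emph <- array(FALSE, shape)
  for (l in 1:5) {
    frac <- spec$emphysema_fraction_per_lobe[l]
    sel <- masks$labels == l
    if (frac <= 0) next
    if (frac >= 1) { emph[sel] <- TRUE; next }
    fv <- field[sel]
    thr <- stats::quantile(fv, probs = 1 - frac, names = FALSE, type = 7)
    emph[sel] <- fv > thr
  }
  hu <- with_seed(derive_seed(spec$random_seed, 12), {
    out <- array(stats::rnorm(prod(shape), mean = 40, sd = 20), shape)  # soft tissue
    inlung <- masks$labels > 0L
    n_par <- sum(inlung & !emph)
    n_emp <- sum(inlung & emph)
    out[inlung & !emph] <- stats::rnorm(n_par, spec$parenchyma_hu_mean,
                                        spec$parenchyma_hu_sd)
    if (n_emp > 0) {
      out[inlung & emph] <- stats::rnorm(n_emp, spec$emphysema_hu_mean,
                                         spec$emphysema_hu_sd)
    }
    out
  })
  voxel_grid(hu, spec$voxel_spacing, "HU")
}

#' Generate a smooth ventilation-fraction map with lobar defects
#'
#' Healthy lung gets a smoothly varying ventilation fraction in about
#' \[0.5, 1\]; in each lobe the requested fraction of voxels — the lower tail
#' of a smooth random field, so defects are contiguous — is set to a
#' near-zero value (signal void). Outside the lungs the map is zero.
#'
#' @param spec a [phantom_spec()].
#' @param masks the subject's [lobar_masks()].
#' @param defect_fractions optional override of the per-lobe defect
#'   fractions (used for the perfusion map of the same subject).
#' @param seed_stream internal stream offset so ventilation and perfusion
#'   maps of one subject are distinct but reproducible.
#' @return `voxel_grid` with role `"ventilation_fraction"`.
#' @export
generate_ventilation_map <- function(spec, masks,
                                     defect_fractions = NULL,
                                     seed_stream = 21) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(masks, "lobar_masks"))
  shape <- spec$grid_shape
  if (!identical(dim(masks$labels), shape)) stop_("masks are not on the spec grid")
  df <- if (is.null(defect_fractions)) {
    spec$ventilation_defect_fraction_per_lobe
  } else check_fractions(defect_fractions, "defect_fractions")
  base_f <- smooth_field(shape, 3, derive_seed(spec$random_seed, seed_stream))
  def_f <- smooth_field(shape, 2, derive_seed(spec$random_seed, seed_stream + 1))
  vent <- array(0, shape)
  inlung <- masks$labels > 0L
  vent[inlung] <- clamp(0.8 + 0.12 * base_f[inlung], 0.5, 1)
  for (l in 1:5) {
    frac <- df[l]
    if (frac <= 0) next
    sel <- masks$labels == l
    fv <- def_f[sel]
    keep <- if (frac >= 1) rep(TRUE, length(fv)) else {
      fv < stats::quantile(fv, probs = frac, names = FALSE, type = 7)
    }
    idx <- which(sel)[keep]
    # defect floor well below 5% of the healthy signal level
    vent[idx] <- 0.01 + 0.005 * def_f[idx]^2
  }
  voxel_grid(clamp(vent, 0, 1), spec$voxel_spacing, "ventilation_fraction")
}

#' Generate a perfusion-fraction map for the same subject
#'
#' Perfusion in emphysematous COPD broadly tracks ventilation; the phantom
#' reuses the ventilation generator with an independent random stream and
#' the same defect burden, so V and Q maps agree in lobar pattern but not
#' voxel-for-voxel.
#'
#' @inheritParams generate_ventilation_map
#' @return `voxel_grid` with role `"ventilation_fraction"`.
#' @export
generate_perfusion_map <- function(spec, masks) {
  generate_ventilation_map(spec, masks, seed_stream = 31)
}

#' Generate the receive-coil flip-angle map
#'
#' A smooth monotone anterior-posterior gradient in the flip angle. The map
#' is linear in `sin(alpha)` along the y (posterior-to-anterior) axis and
#' anchored so the first-volume signal ratio between the anterior and
#' posterior faces, `sin(alpha_max) / sin(alpha_min)`, equals
#' `coil_ap_ratio` exactly, with the nominal flip angle at the geometric
#' mean. With `coil_ap_ratio = 1` the map is constant at `nominal_alpha`.
#'
#' @param spec a [phantom_spec()].
#' @return `voxel_grid` with role `"alpha_deg"`.
#' @export
generate_coil_alpha_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  R <- spec$coil_ap_ratio
  if (R < 1) stop_("coil_ap_ratio must be >= 1 (got %g)", R)
  shape <- spec$grid_shape
  s0 <- sin(spec$nominal_alpha * pi / 180)
  s_min <- s0 / sqrt(R)
  s_max <- s0 * sqrt(R)
  if (s_max >= 1) {
    stop_("coil_ap_ratio %g with nominal_alpha %g pushes the flip angle past 90 degrees",
          R, spec$nominal_alpha)
  }
  ny <- shape[2]
  yfrac <- if (ny == 1L) 0.5 else (seq_len(ny) - 1) / (ny - 1)
  alpha_y <- asin(s_min + (s_max - s_min) * yfrac) * 180 / pi
  if (R == 1) alpha_y <- rep(spec$nominal_alpha, ny)
  a <- array(rep(rep(alpha_y, each = shape[1]), times = shape[3]), shape)
  voxel_grid(a, spec$voxel_spacing, "alpha_deg")
}

#' Degrade a ventilation/perfusion pair to SPECT-like count volumes
#'
#' Emulates the SPECT system: Gaussian blur to the system resolution
#' (default 10 mm FWHM), resampling to the SPECT pixel grid (default 4 mm),
#' scaling to the expected total count, and Poisson noise. Blur and
#' resampling conserve the expected total signal (checked to 0.5% in the
#' test-suite); Poisson noise is applied last.
#'
#' @param vent,perf nonnegative `voxel_grid` maps on the phantom grid.
#' @param spec a [phantom_spec()].
#' @return list with elements `v` and `q`, both `voxel_grid` of role
#'   `"spect_counts"` on the SPECT grid.
#' @export
generate_spect_pair <- function(vent, perf, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  list(
    v = spect_degrade(vent, spec, stream = 41),
    q = spect_degrade(perf, spec, stream = 42)
  )
}

#' Apply the SPECT degradation model to one activity map
#'
#' @param vol nonnegative `voxel_grid` activity map.
#' @param spec a [phantom_spec()].
#' @param stream internal random stream offset for the Poisson draw.
#' @param poisson apply Poisson noise (disable to inspect the expected image).
#' @return `voxel_grid` of role `"spect_counts"`.
#' @export
spect_degrade <- function(vol, spec, stream = 41, poisson = TRUE) {
  stopifnot(inherits(vol, "voxel_grid"))
  if (any(vol$values < 0)) stop_("SPECT input map has negative values")
  sigma_mm <- spec$spect_resolution_fwhm / (2 * sqrt(2 * log(2)))
  blurred <- gaussian_smooth3d(vol$values, sigma_mm / vol$spacing)
  res <- resample_volume(voxel_grid(blurred, vol$spacing, "spect_counts"),
                         rep(spec$spect_pixel, 3), conserve_sum = TRUE)
  tot <- sum(res$values)
  expected <- if (tot > 0) res$values * (spec$spect_total_counts / tot) else res$values
  counts <- if (poisson) {
    with_seed(derive_seed(spec$random_seed, stream),
              array(stats::rpois(length(expected), expected), dim(expected)))
  } else expected
  voxel_grid(counts * 1.0, res$spacing, "spect_counts")
}

#' Generate one complete phantom subject
#'
#' Runs every phantom generator for one spec: lobe masks, CT, ventilation
#' and perfusion maps, coil flip-angle map, and the SPECT pair.
#'
#' @param spec a [phantom_spec()].
#' @param with_spect generate SPECT volumes (disable to emulate a subject
#'   who was not scanned with SPECT).
#' @return list with `spec`, `masks`, `ct`, `vent`, `perf`, `alpha_map`,
#'   and (optionally) `spect_v`, `spect_q`.
#' @export
generate_phantom_subject <- function(spec, with_spect = TRUE) {
  masks <- generate_lobe_masks(spec)
  ct <- generate_ct_volume(spec, masks)
  vent <- generate_ventilation_map(spec, masks)
  perf <- generate_perfusion_map(spec, masks)
  alpha_map <- generate_coil_alpha_map(spec)
  out <- list(spec = spec, masks = masks, ct = ct, vent = vent, perf = perf,
              alpha_map = alpha_map)
  if (with_spect) {
    sp <- generate_spect_pair(vent, perf, spec)
    out$spect_v <- sp$v
    out$spect_q <- sp$q
  }
  out
}

#' Generate a phantom cohort with graded disease severity
#'
#' Builds `n_subjects` phantom specs whose lobar emphysema burden scales a
#' lower-lobe-predominant base pattern by a subject severity drawn evenly
#' over a stated range, with per-lobe jitter. Ventilation-defect burden is
#' constructed as an increasing function of emphysema burden (plus noise),
#' so across the cohort emphysema drives ventilation loss by construction.
#' Spirometry-like covariates (FEV1 percent-predicted and FEV1/FVC) are
#' generated as noisy decreasing functions of the whole-lung defect burden —
#' a synthetic construction standing in for lung-function tests.
#'
#' @param n_subjects number of subjects (default 12).
#' @param base_spec template [phantom_spec()]; per-subject specs share its
#'   geometry and physics and differ in burden fractions and seed.
#' @param seed cohort-level seed.
#' @return list with `specs` (list of phantom_spec) and `covariates`
#'   (data.frame: subject_id, severity, fev1_pct_pred, fev1_fvc_pct).
#' @export
generate_phantom_cohort <- function(n_subjects = 12, base_spec = phantom_spec(),
                                    seed = 1L) {
  stopifnot(n_subjects >= 1)
  base_pattern <- c(RUL = 0.5, RML = 0.6, RLL = 1.0, LUL = 0.6, LLL = 0.85)
  severity <- seq(0.08, 0.85, length.out = n_subjects)
  params <- with_seed(derive_seed(seed, 1), {
    lapply(seq_len(n_subjects), function(i) {
      emph <- clamp(severity[i] * base_pattern *
                      exp(stats::rnorm(5, 0, 0.15)), 0, 0.6)
      defect <- clamp(1.1 * emph + 0.02 + stats::rnorm(5, 0, 0.02), 0, 0.9)
      list(emph = emph, defect = defect)
    })
  })
  specs <- lapply(seq_len(n_subjects), function(i) {
    sp <- base_spec
    sp$emphysema_fraction_per_lobe <- check_fractions(
      params[[i]]$emph, "emphysema_fraction_per_lobe")
    sp$ventilation_defect_fraction_per_lobe <- check_fractions(
      params[[i]]$defect, "ventilation_defect_fraction_per_lobe")
    sp$random_seed <- as.integer(derive_seed(seed, 100 + i))
    sp
  })
  wl_defect <- vapply(params, function(p) mean(p$defect), numeric(1))
  cov <- with_seed(derive_seed(seed, 2), data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    severity = severity,
    fev1_pct_pred = clamp(95 - 90 * wl_defect + stats::rnorm(n_subjects, 0, 4),
                          15, 110),
    fev1_fvc_pct = clamp(85 - 70 * wl_defect + stats::rnorm(n_subjects, 0, 3),
                         20, 95)
  ))
  list(specs = specs, covariates = cov)
}
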