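#' Acquisition schedule of a breath-hold time series
#'
#' Ties each volume of the time series to the elapsed time at which it was
#' acquired and the number of RF excitations a voxel has experienced per
#' volume. The default mirrors a rapid spiral breath-hold protocol: 8
#' volumes over ~20 s (one every 2.5 s), each built from 8 spiral
#' interleaves, i.e. 8 RF pulses per voxel per volume.
#'
#' @param volume_times numeric, strictly increasing elapsed times (s) of the
#'   volumes; the first is conventionally 0.
#' @param pulses_per_volume integer >= 1, RF pulses a voxel experiences per
#'   volume (one per interleave).
#' @param slice_time_offsets optional per-slice acquisition offsets (s);
#'   default all zero (simultaneous-slice idealization).
#' @return An object of class `acq_schedule`.
#' @export
acq_schedule <- function(volume_times = seq(0, by = 2.5, length.out = 8),
                         pulses_per_volume = 8L,
                         slice_time_offsets = NULL) {
  volume_times <- as.numeric(volume_times)
  n <- length(volume_times)
  if (n < 1L) stop_("schedule needs at least one volume")
  if (any(diff(volume_times) <= 0)) {
    stop_("volume_times must be strictly increasing")
  }
  pulses_per_volume <- as.integer(pulses_per_volume)
  if (pulses_per_volume < 1L) stop_("pulses_per_volume must be >= 1")
  dt <- diff(volume_times)
  uniform <- n <= 2L || max(abs(dt - dt[1])) < 1e-9 * max(dt[1], 1)
  structure(list(
    n_volumes = n,
    volume_times = volume_times,
    pulses_per_volume = pulses_per_volume,
    slice_time_offsets = slice_time_offsets,
    uniform_flag = uniform
  ), class = "acq_schedule")
}

#' A non-uniform, identifiable variant of the default schedule
#'
#' Under uniform volume spacing with a constant pulse count, per-pulse
#' depletion (`cos(alpha)` per pulse) and T1 relaxation collapse into a
#' single exponential in the volume index and cannot be separated. This
#' schedule keeps 8 volumes and 8 pulses per volume but spaces the volumes
#' non-uniformly (clustered early, stretched late) so the two decay
#' mechanisms act on distinguishable time patterns and all three model
#' parameters are identifiable.
#'
#' @param pulses_per_volume RF pulses per volume (default 8).
#' @return An `acq_schedule` with volume times 0, 0.6, 1.2, 2.5, 5, 9, 14, 20 s.
#' @export
identifiable_schedule <- function(pulses_per_volume = 8L) {
  acq_schedule(volume_times = c(0, 0.6, 1.2, 2.5, 5, 9, 14, 20),
               pulses_per_volume = pulses_per_volume)
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf("<acq_schedule: %d volumes at t = %s s, %d pulses/volume%s>\n",
              x$n_volumes, paste(signif(x$volume_times, 4), collapse = ", "),
              x$pulses_per_volume,
              if (x$uniform_flag) " (uniform)" else ""))
  invisible(x)
}

#' Hyperpolarized signal-decay model
#'
#' Expected signal of a non-renewable hyperpolarized magnetization pool at
#' volume `k` of a breath-hold time series:
#' \deqn{S_k = S_0 \sin\alpha \; \cos(\alpha)^{P (k-1)} \; e^{-t_k / T_1}}
#' Each RF pulse reads out `sin(alpha)` of the available magnetization and
#' leaves `cos(alpha)` of it; after `k - 1` completed volumes a voxel has
#' experienced `P (k-1)` pulses, and the magnetization has additionally
#' relaxed for the elapsed time `t_k`.
#'
#' @param S0 initial signal amplitude (a.u.), >= 0.
#' @param alpha flip angle in degrees, in (0, 90).
#' @param T1 longitudinal decay time (s), > 0.
#' @param schedule an [acq_schedule()].
#' @param k volume index (1-based); defaults to all volumes.
#' @return numeric vector of expected signals at the requested volumes.
#' @export
hpx_signal_model <- function(S0, alpha, T1, schedule,
                             k = seq_len(schedule$n_volumes)) {
  stopifnot(inherits(schedule, "acq_schedule"))
  if (any(alpha <= 0) || any(alpha >= 90)) {
    stop_("flip angle must be in (0, 90) degrees, got %g", alpha[1])
  }
  if (any(T1 <= 0)) stop_("T1 must be positive, got %g", T1[1])
  if (any(S0 < 0)) stop_("S0 must be nonnegative")
  if (any(k < 1L) || any(k > schedule$n_volumes)) {
    stop_("volume index k out of range 1..%d", schedule$n_volumes)
  }
  a <- alpha * pi / 180
  P <- schedule$pulses_per_volume
  tk <- schedule$volume_times[k]
  S0 * sin(a) * cos(a)^(P * (k - 1)) * exp(-tk / T1)
}

#' Time-series container
#'
#' An ordered set of gas-MRI volumes sharing one grid, plus the acquisition
#' schedule tying each volume to elapsed time and cumulative RF pulses.
#'
#' @param volumes list of `voxel_grid` objects with role `"hpx_signal"`,
#'   all on one grid.
#' @param schedule an [acq_schedule()] with `n_volumes == length(volumes)`.
#' @return An object of class `hpx_timeseries`.
#' @export
hpx_timeseries <- function(volumes, schedule) {
  stopifnot(inherits(schedule, "acq_schedule"), is.list(volumes))
  if (length(volumes) != schedule$n_volumes) {
    stop_("got %d volumes for a %d-volume schedule",
          length(volumes), schedule$n_volumes)
  }
  for (v in volumes) {
    if (!inherits(v, "voxel_grid")) stop_("volumes must be voxel_grid objects")
    assert_same_grid(volumes[[1]], v, "time-series volumes")
  }
  structure(list(volumes = volumes, schedule = schedule),
            class = "hpx_timeseries")
}

#' @export
print.hpx_timeseries <- function(x, ...) {
  d <- dim(x$volumes[[1]]$values)
  cat(sprintf("<hpx_timeseries: %d volumes of %d x %d x %d>\n",
              length(x$volumes), d[1], d[2], d[3]))
  invisible(x)
}

#' Forward-simulate a hyperpolarized breath-hold time series
#'
#' Applies [hpx_signal_model()] voxelwise: the initial amplitude is
#' `signal_scale * ventilation`, the flip angle comes from the coil map, and
#' T1 is a scalar (or a map on the same grid). Zero-mean Gaussian noise of
#' s.d. `noise_sd` is added independently to every voxel of every volume;
#' negative values are kept (real-valued images, no magnitude bias).
#'
#' @param vent `voxel_grid` ventilation map (role `"ventilation_fraction"`).
#' @param alpha_map `voxel_grid` flip-angle map (role `"alpha_deg"`) on the
#'   same grid.
#' @param T1 scalar T1 in seconds, or a `voxel_grid` T1 map.
#' @param schedule an [acq_schedule()].
#' @param noise_sd additive Gaussian noise s.d. (a.u.), >= 0.
#' @param seed integer seed for the noise draw.
#' @param signal_scale amplitude multiplying the ventilation fraction.
#' @return An [hpx_timeseries()].
#' @export
simulate_hpx_timeseries <- function(vent, alpha_map, T1, schedule,
                                    noise_sd = 0, seed = 1L,
                                    signal_scale = 1) {
  stopifnot(inherits(vent, "voxel_grid"), inherits(alpha_map, "voxel_grid"),
            inherits(schedule, "acq_schedule"))
  assert_same_grid(vent, alpha_map, "ventilation and flip-angle maps")
  if (noise_sd < 0) stop_("noise_sd must be nonnegative")
  T1v <- if (inherits(T1, "voxel_grid")) {
    assert_same_grid(vent, T1, "ventilation and T1 maps")
    T1$values
  } else {
    if (T1 <= 0) stop_("T1 must be positive")
    T1
  }
  a <- alpha_map$values * pi / 180
  if (any(a <= 0) || any(a >= pi / 2)) {
    stop_("flip-angle map must be strictly inside (0, 90) degrees")
  }
  S0 <- signal_scale * vent$values
  P <- schedule$pulses_per_volume
  sina <- sin(a)
  cosa <- cos(a)
  vols <- vector("list", schedule$n_volumes)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(S0) * schedule$n_volumes, 0, noise_sd))
  } else NULL
  for (k in seq_len(schedule$n_volumes)) {
    sig <- S0 * sina * cosa^(P * (k - 1)) *
      exp(-schedule$volume_times[k] / T1v)
    if (!is.null(noise)) {
      off <- (k - 1) * length(S0)
      sig <- sig + array(noise[(off + 1):(off + length(S0))], dim(S0))
    }
    vols[[k]] <- voxel_grid(sig, vent$spacing, "hpx_signal")
  }
  hpx_timeseries(vols, schedule)
}
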