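#' CT percent-emphysema per lobe
#'
#' The structural emphysema index: for each lobe, 100 times the fraction of
#' lobe voxels with attenuation strictly below the threshold (default
#' -950 HU). A `whole_lung` entry uses all lung voxels (the union of the
#' five lobes).
#'
#' @param ct `voxel_grid` with role `"HU"`.
#' @param masks [lobar_masks()] on the same grid.
#' @param threshold_hu attenuation cut in HU (default -950).
#' @return named numeric vector: five lobes plus `whole_lung`, in percent.
#' @export
emphysema_pct <- function(ct, masks, threshold_hu = -950) {
  stopifnot(inherits(ct, "voxel_grid"), inherits(masks, "lobar_masks"))
  if (!identical(dim(ct$values), dim(masks$labels))) {
    stop_("CT and masks are on different grids")
  }
  low <- ct$values < threshold_hu
  lab <- masks$labels
  counts <- lobe_voxel_counts(masks)
  pct <- vapply(1:5, function(l) 100 * sum(low[lab == l]) / counts[l], numeric(1))
  wl <- 100 * sum(low[lab > 0L]) / sum(counts)
  stats::setNames(c(pct, wl), c(LOBE_NAMES, "whole_lung"))
}

#' Relative lobar percent-ventilation (or perfusion)
#'
#' Each lobe's share of the total lung signal:
#' `100 * sum(signal in lobe) / sum(signal over all five lobes)`. The
#' denominator is the whole-lung signal sum, which makes the five lobar
#' percentages sum to exactly 100 by construction — the convention shared
#' by SPECT lobar analysis.
#'
#' @param signal `voxel_grid` of gas-MRI signal or SPECT counts,
#'   nonnegative inside the lungs.
#' @param masks [lobar_masks()] on the same grid.
#' @return named numeric vector over the five lobes, in percent, summing
#'   to 100.
#' @export
relative_ventilation_pct <- function(signal, masks) {
  stopifnot(inherits(signal, "voxel_grid"), inherits(masks, "lobar_masks"))
  if (!identical(dim(signal$values), dim(masks$labels))) {
    stop_("signal and masks are on different grids")
  }
  lab <- masks$labels
  inlung <- lab > 0L
  if (any(signal$values[inlung] < 0)) {
    stop_("negative signal inside the lungs; relative shares undefined")
  }
  sums <- vapply(1:5, function(l) sum(signal$values[lab == l]), numeric(1))
  total <- sum(sums)
  if (total <= 0) stop_("total lung signal is zero; relative shares undefined")
  stats::setNames(100 * sums / total, LOBE_NAMES)
}

#' Absolute percent-ventilation (defect) score
#'
#' Signal-threshold defect scoring of a decay-corrected ventilation image:
#' the threshold is `frac` (default 5%) of a whole-lung reference signal
#' level, and each lobe's score is 100 times the fraction of its voxels
#' strictly below the threshold. Higher scores mean more ventilation
#' defect. The reference level is configurable: `"p99"` (default, the 99th
#' percentile of lung-voxel signal — a hot-pixel-robust maximum), `"max"`,
#' or `"mean"`.
#'
#' @param signal `voxel_grid` decay-corrected gas-MRI signal.
#' @param masks [lobar_masks()] on the same grid.
#' @param frac threshold as a fraction of the reference level (default 0.05).
#' @param reference reference-level mode: `"p99"`, `"max"` or `"mean"`.
#' @return named numeric vector: five lobes plus `whole_lung`, in percent.
#' @export
absolute_ventilation_defect_pct <- function(signal, masks, frac = 0.05,
                                            reference = c("p99", "max", "mean")) {
  stopifnot(inherits(signal, "voxel_grid"), inherits(masks, "lobar_masks"))
  reference <- match.arg(reference)
  if (!identical(dim(signal$values), dim(masks$labels))) {
    stop_("signal and masks are on different grids")
  }
  lab <- masks$labels
  inlung <- lab > 0L
  lung_vals <- signal$values[inlung]
  if (all(lung_vals == 0)) stop_("all-zero signal volume; defect score undefined")
  ref <- switch(reference,
    p99 = stats::quantile(lung_vals, 0.99, names = FALSE, type = 7),
    max = max(lung_vals),
    mean = mean(lung_vals))
  thr <- frac * ref
  low <- signal$values < thr
  counts <- lobe_voxel_counts(masks)
  pct <- vapply(1:5, function(l) 100 * sum(low[lab == l]) / counts[l], numeric(1))
  wl <- 100 * sum(low[inlung]) / sum(counts)
  stats::setNames(c(pct, wl), c(LOBE_NAMES, "whole_lung"))
}

#' Relative lobar SPECT ventilation/perfusion percentages
#'
#' The same lobar-share formula as [relative_ventilation_pct()] applied to
#' a SPECT count volume, after nearest-neighbour resampling of the lobe
#' masks onto the SPECT grid (done by the caller or here when grids
#' differ).
#'
#' @param spect `voxel_grid` with role `"spect_counts"`.
#' @param masks [lobar_masks()]; resampled to the SPECT grid if needed.
#' @return named numeric vector over the five lobes, in percent.
#' @export
spect_lobar_pct <- function(spect, masks) {
  stopifnot(inherits(spect, "voxel_grid"), inherits(masks, "lobar_masks"))
  if (!identical(dim(spect$values), dim(masks$labels))) {
    masks <- resample_mask(masks, spect)
  }
  relative_ventilation_pct(spect, masks)
}

#' Assemble the lobar score table for one subject
#'
#' One row per lobe plus a whole-lung row, with the four scores the
#' pipeline compares: CT percent-emphysema, relative and absolute
#' gas-MRI percent-ventilation, and SPECT ventilation/perfusion shares.
#' Modalities not supplied give NA columns (a subject may lack SPECT).
#'
#' @param subject_id subject identifier string.
#' @param ct `voxel_grid` HU volume, or NULL.
#' @param hpx_corrected decay-corrected gas-MRI `voxel_grid`, or NULL.
#' @param spect_v,spect_q SPECT count `voxel_grid`s, or NULL.
#' @param masks [lobar_masks()] on the CT/gas-MRI grid.
#' @param threshold_hu,frac,reference scoring options, see
#'   [emphysema_pct()] and [absolute_ventilation_defect_pct()].
#' @return data.frame with columns subject_id, lobe, ct_emphysema_pct,
#'   hpx_rel_vent_pct, hpx_abs_vent_pct, spect_vent_pct, spect_perf_pct.
#' @export
lobar_score_table <- function(subject_id, ct = NULL, hpx_corrected = NULL,
                              spect_v = NULL, spect_q = NULL, masks,
                              threshold_hu = -950, frac = 0.05,
                              reference = "p99") {
  stopifnot(inherits(masks, "lobar_masks"))
  rows <- c(LOBE_NAMES, "whole_lung")
  na6 <- stats::setNames(rep(NA_real_, 6), rows)
  pad5 <- function(x) c(x, whole_lung = NA_real_)
  emph <- if (is.null(ct)) na6 else emphysema_pct(ct, masks, threshold_hu)
  rel <- if (is.null(hpx_corrected)) na6 else {
    pad5(relative_ventilation_pct(hpx_corrected, masks))
  }
  abs_ <- if (is.null(hpx_corrected)) na6 else {
    absolute_ventilation_defect_pct(hpx_corrected, masks, frac, reference)
  }
  sv <- if (is.null(spect_v)) na6 else pad5(spect_lobar_pct(spect_v, masks))
  sq <- if (is.null(spect_q)) na6 else pad5(spect_lobar_pct(spect_q, masks))
  data.frame(
    subject_id = subject_id,
    lobe = rows,
    ct_emphysema_pct = unname(emph[rows]),
    hpx_rel_vent_pct = unname(rel[rows]),
    hpx_abs_vent_pct = unname(abs_[rows]),
    spect_vent_pct = unname(sv[rows]),
    spect_perf_pct = unname(sq[rows]),
    stringsAsFactors = FALSE
  )
}
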