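# Grid resampling. All modalities of one phantom subject share a world
# frame with origin at the grid corner and voxel centres at
# (i + 0.5) * spacing (0-based i), so resampling needs no registration.

#' Nearest-neighbour resampling of lobe masks onto another grid
#'
#' Each target voxel takes the label of the source voxel containing its
#' centre (nearest neighbour on cell-centred grids); points outside the
#' source extent become background. Labels are never interpolated, so the
#' label set after resampling is a subset of the source label set. A lobe
#' that vanishes on the target grid is an error.
#'
#' @param masks a [lobar_masks()].
#' @param target a `voxel_grid` (or `lobar_masks`) defining the target grid.
#' @return a [lobar_masks()] on the target grid.
#' @export
resample_mask <- function(masks, target) {
  stopifnot(inherits(masks, "lobar_masks"))
  tdim <- if (inherits(target, "voxel_grid")) dim(target$values) else dim(target$labels)
  tsp <- target$spacing
  sdim <- dim(masks$labels)
  ssp <- masks$spacing
  axis_map <- function(nt, spt, ns, sps) {
    w <- (seq_len(nt) - 0.5) * spt
    i <- floor(w / sps) + 1L
    i[i < 1L | i > ns] <- NA_integer_
    i
  }
  mx <- axis_map(tdim[1], tsp[1], sdim[1], ssp[1])
  my <- axis_map(tdim[2], tsp[2], sdim[2], ssp[2])
  mz <- axis_map(tdim[3], tsp[3], sdim[3], ssp[3])
  okx <- !is.na(mx); oky <- !is.na(my); okz <- !is.na(mz)
  labels <- array(0L, tdim)
  if (any(okx) && any(oky) && any(okz)) {
    labels[okx, oky, okz] <- masks$labels[mx[okx], my[oky], mz[okz]]
  }
  counts <- tabulate(labels, nbins = 5L)
  if (any(counts == 0L)) {
    stop_("lobe %s vanished at the target resolution (%s mm); use a finer target grid",
          LOBE_NAMES[which(counts == 0L)[1]], paste(tsp, collapse = "x"))
  }
  lobar_masks(labels, tsp)
}

#' Trilinear resampling of a scalar volume to a new voxel spacing
#'
#' Samples the source volume (zero outside its extent) at the centres of a
#' target grid covering the same physical extent. With
#' `conserve_sum = TRUE` the result is scaled by the voxel-volume ratio so
#' the integral (total counts) is preserved for smooth fields.
#'
#' @param vol a `voxel_grid`.
#' @param target_spacing numeric length-3 spacing of the target grid (mm).
#' @param conserve_sum preserve the volume integral (for count data).
#' @return a `voxel_grid` on the target grid with the same role.
#' @export
resample_volume <- function(vol, target_spacing, conserve_sum = FALSE) {
  stopifnot(inherits(vol, "voxel_grid"))
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(target_spacing <= 0)) stop_("target spacing must be positive")
  sdim <- dim(vol$values)
  ssp <- vol$spacing
  extent <- sdim * ssp
  tdim <- pmax(1L, as.integer(round(extent / target_spacing)))
  # continuous (1-based) source index of each target voxel centre, per axis
  pos <- lapply(1:3, function(ax) {
    ((seq_len(tdim[ax]) - 0.5) * target_spacing[ax]) / ssp[ax] + 0.5
  })
  i0 <- lapply(pos, floor)
  fr <- Map(function(p, i) p - i, pos, i0)
  nx <- tdim[1]; ny <- tdim[2]; nz <- tdim[3]
  ex <- function(v, ax) {  # expand an axis vector to the full target grid
    switch(ax,
           rep(v, times = ny * nz),
           rep(rep(v, each = nx), times = nz),
           rep(v, each = nx * ny))
  }
  gather <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= sdim[1] & iy >= 1 & iy <= sdim[2] & iz >= 1 & iz <= sdim[3]
    out <- numeric(nx * ny * nz)
    if (any(ok)) {
      lin <- (iz[ok] - 1) * sdim[1] * sdim[2] + (iy[ok] - 1) * sdim[1] + ix[ok]
      out[ok] <- vol$values[lin]
    }
    out
  }
  i0x <- ex(i0[[1]], 1); i0y <- ex(i0[[2]], 2); i0z <- ex(i0[[3]], 3)
  fx <- ex(fr[[1]], 1); fy <- ex(fr[[2]], 2); fz <- ex(fr[[3]], 3)
  acc <- numeric(nx * ny * nz)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    acc <- acc + w * gather(i0x + dx, i0y + dy, i0z + dz)
  }
  out <- array(acc, tdim)
  if (conserve_sum) out <- out * prod(target_spacing) / prod(ssp)
  voxel_grid(out, target_spacing, vol$role)
}
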