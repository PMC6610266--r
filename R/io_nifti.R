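# Minimal NIfTI-1 reader/writer.
#
# Only what this pipeline needs: single-file .nii / .nii.gz, 3-D or 4-D,
# datatypes uint8 / int16 / int32 / float32 / float64, no scaling
# (scl_slope 1, scl_inter 0), no extensions. Orientation is stored as a
# diagonal sform (RAS axis order matching the package's x/y/z convention);
# both endiannesses are read, little-endian is written.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Write a raw NIfTI-1 file from an array (3-D or 4-D) and spacing.
write_nifti_array <- function(arr, spacing, path, datatype = "float64",
                              time_step = 0) {
  dt <- NIFTI_DTYPES[[datatype]]
  if (is.null(dt)) stop_("unsupported NIfTI datatype '%s'", datatype)
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L)) stop_("only 3-D or 4-D volumes are written")
  con <- open_nifti_con(path, "wb")
  on.exit(close(con))
  dims <- c(nd, dim(arr), rep(1L, 7 - nd))
  pixdim <- c(1, spacing, if (nd == 4L) time_step else numeric(0))
  pixdim <- c(pixdim, rep(0, 8L - length(pixdim)))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                      # sizeof_hdr
  w_raw(36L)                       # data_type..dim_info
  w_i16(dims)                      # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)     # intent_p1..3, intent_code
  w_i16(dt$code); w_i16(dt$bitpix); w_i16(0L)  # datatype, bitpix, slice_start
  w_f32(pixdim)                    # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)             # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  desc <- charToRaw("xelobe phantom pipeline volume")
  w_raw2 <- function(r, n) writeBin(c(r, raw(n - length(r))), con)
  w_raw2(desc, 80L)                # descrip
  w_raw(24L)                       # aux_file
  w_i16(0L); w_i16(2L)             # qform_code 0, sform_code 2 (aligned)
  w_f32(rep(0, 6))                 # quatern b,c,d + qoffset x,y,z
  w_f32(c(spacing[1], 0, 0, 0))    # srow_x
  w_f32(c(0, spacing[2], 0, 0))    # srow_y
  w_f32(c(0, 0, spacing[3], 0))    # srow_z
  w_raw(16L)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                        # extension flag: none
  vals <- as.vector(arr)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

# Read a raw NIfTI-1 file; returns list(values, spacing, ndim, time_step).
read_nifti_array <- function(path) {
  con <- open_nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  if (length(hdr) < 348) stop_("'%s' is not a NIfTI-1 file (truncated header)", path)
  rd <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, endian) != 348L) {
    endian <- "big"
    if (rd(0, "integer", 1, 4, endian) != 348L) {
      stop_("'%s' is not a NIfTI-1 file (sizeof_hdr != 348)", path)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop_("'%s': unsupported NIfTI magic '%s'", path, magic)
  dims <- rd(40, "integer", 8, 2, endian)
  nd <- dims[1]
  if (!nd %in% c(3L, 4L)) {
    stop_("'%s' is %d-dimensional; this reader handles 3-D and 4-D volumes",
          path, nd)
  }
  datatype <- rd(70, "integer", 1, 2, endian)
  dt_name <- names(Filter(function(d) d$code == datatype, NIFTI_DTYPES))
  if (!length(dt_name)) stop_("'%s': unsupported NIfTI datatype code %d", path, datatype)
  dt <- NIFTI_DTYPES[[dt_name]]
  pixdim <- rd(76, "double", 8, 4, endian)
  vox_offset <- rd(108, "double", 1, 4, endian)
  scl_slope <- rd(112, "double", 1, 4, endian)
  scl_inter <- rd(116, "double", 1, 4, endian)
  shape <- dims[2:(nd + 1)]
  n_vals <- prod(shape)
  if (vox_offset > 352) readBin(con, "raw", n = vox_offset - 352)
  vals <- if (dt_name == "uint8") {
    as.double(readBin(con, "integer", n = n_vals, size = 1, signed = FALSE))
  } else if (dt$what == "integer") {
    as.double(readBin(con, "integer", n = n_vals, size = dt$size, endian = endian))
  } else {
    readBin(con, "double", n = n_vals, size = dt$size, endian = endian)
  }
  if (length(vals) != n_vals) stop_("'%s': data shorter than header dims", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(values = array(vals, shape), spacing = pixdim[2:4], ndim = nd,
       time_step = if (nd == 4L) pixdim[5] else NA_real_)
}

#' Read a 3-D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param role role tag for the returned grid (see [voxel_grid()]).
#' @return a `voxel_grid`.
#' @export
read_volume <- function(path, role = "hpx_signal") {
  nif <- read_nifti_array(path)
  if (nif$ndim != 3L) {
    stop_("'%s' holds a %d-D image; expected a 3-D volume (use read_timeseries for 4-D)",
          path, nif$ndim)
  }
  voxel_grid(nif$values, nif$spacing, role)
}

#' Write a 3-D volume to a NIfTI-1 file
#'
#' @param vol a `voxel_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype on-disk type; `"float64"` (default) round-trips values
#'   bit-exactly, `"int32"` suits label masks.
#' @export
write_volume <- function(vol, path, datatype = "float64") {
  stopifnot(inherits(vol, "voxel_grid"))
  write_nifti_array(vol$values, vol$spacing, path, datatype)
  invisible(path)
}

#' Read lobe masks from an integer-label NIfTI file
#' @param path path to the label volume.
#' @return a [lobar_masks()].
#' @export
read_masks <- function(path) {
  nif <- read_nifti_array(path)
  if (nif$ndim != 3L) stop_("'%s': mask volume must be 3-D", path)
  lobar_masks(array(as.integer(round(nif$values)), dim(nif$values)), nif$spacing)
}

#' Write lobe masks as an integer-label NIfTI file
#' @param masks a [lobar_masks()].
#' @param path output path.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "lobar_masks"))
  write_nifti_array(masks$labels, masks$spacing, path, "int32")
  invisible(path)
}

#' Write a breath-hold time series as 4-D NIfTI plus a JSON schedule sidecar
#'
#' @param ts an [hpx_timeseries()].
#' @param path output `.nii`/`.nii.gz` path; the sidecar is written next to
#'   it with extension `.schedule.json`.
#' @return invisibly, `c(volume = path, schedule = sidecar_path)`.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "hpx_timeseries"))
  d <- dim(ts$volumes[[1]]$values)
  arr <- array(0, c(d, length(ts$volumes)))
  for (k in seq_along(ts$volumes)) arr[, , , k] <- ts$volumes[[k]]$values
  dt <- diff(ts$schedule$volume_times)
  write_nifti_array(arr, ts$volumes[[1]]$spacing, path, "float64",
                    time_step = if (length(dt)) dt[1] else 0)
  side <- schedule_sidecar_path(path)
  jsonlite::write_json(list(
    volume_times = ts$schedule$volume_times,
    pulses_per_volume = ts$schedule$pulses_per_volume,
    slice_time_offsets = ts$schedule$slice_time_offsets
  ), side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(volume = path, schedule = side))
}

schedule_sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".schedule.json", path)
}

#' Read a 4-D time series written by [write_timeseries()]
#'
#' @param path path to the 4-D NIfTI file; the `.schedule.json` sidecar
#'   must sit next to it (or be given explicitly).
#' @param schedule_path optional explicit sidecar path.
#' @return an [hpx_timeseries()].
#' @export
read_timeseries <- function(path, schedule_path = NULL) {
  nif <- read_nifti_array(path)
  if (nif$ndim != 4L) stop_("'%s' is not a 4-D time series", path)
  side <- schedule_path %||% schedule_sidecar_path(path)
  if (!file.exists(side)) stop_("schedule sidecar '%s' not found", side)
  sj <- jsonlite::fromJSON(side)
  sched <- acq_schedule(volume_times = sj$volume_times,
                        pulses_per_volume = sj$pulses_per_volume,
                        slice_time_offsets = sj$slice_time_offsets)
  nt <- dim(nif$values)[4]
  if (nt != sched$n_volumes) {
    stop_("'%s' has %d volumes but the sidecar schedule has %d", path, nt,
          sched$n_volumes)
  }
  vols <- lapply(seq_len(nt), function(k) {
    voxel_grid(nif$values[, , , k], nif$spacing, "hpx_signal")
  })
  hpx_timeseries(vols, sched)
}
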