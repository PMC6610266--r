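#' Scalar 3-D image volume with voxel spacing
#'
#' The basic container shared by every stage of the pipeline. A
#' `voxel_grid` holds one scalar value per voxel plus the physical voxel
#' spacing in millimetres and a role tag saying what the values mean
#' (Hounsfield units, hyperpolarized-gas signal, SPECT counts, ventilation
#' fraction, or a flip-angle map in degrees).
#'
#' Conventions used throughout the package: voxel indices are 0-based in
#' world-coordinate formulas, axis order is `x` = left-to-right,
#' `y` = posterior-to-anterior, `z` = inferior-to-superior, and a voxel
#' centre sits at `(i + 0.5) * spacing` in a world frame shared by all
#' modalities of one subject.
#'
#' @param values numeric 3-D array.
#' @param spacing numeric length-3 voxel spacing in mm, all positive.
#' @param role one of `"HU"`, `"hpx_signal"`, `"spect_counts"`,
#'   `"ventilation_fraction"`, `"alpha_deg"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, role) {
  role <- match.arg(role, c("HU", "hpx_signal", "spect_counts",
                            "ventilation_fraction", "alpha_deg"))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_("voxel_grid values must be a 3-D array, got %s dimensions",
          length(dim(values)) %||% "no")
  }
  if (!all(is.finite(values))) stop_("voxel_grid values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_("spacing must be 3 positive finite numbers (mm)")
  }
  structure(list(values = values, spacing = spacing, role = role),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid %s: %d x %d x %d @ %.2f x %.2f x %.2f mm, range [%.4g, %.4g]>\n",
              x$role, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9))
}

assert_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop_("%s are on different grids (%s vs %s)", what,
          paste(dim(a$values), collapse = "x"),
          paste(dim(b$values), collapse = "x"))
  }
  invisible(TRUE)
}

#' Lobe names in canonical order
#'
#' Right upper, right middle, right lower, left upper, left lower. Integer
#' labels 1..5 in the mask volume follow this order; 0 is background.
#' @export
LOBE_NAMES <- c("RUL", "RML", "RLL", "LUL", "LLL")

#' Five-lobe label mask set
#'
#' Integer label volume with values 0 (background) and 1..5 for the lobes
#' RUL, RML, RLL, LUL, LLL, plus the voxel spacing of its grid.
#'
#' @param labels integer 3-D array with values in 0..5.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return An object of class `lobar_masks`.
#' @export
lobar_masks <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop_("lobar_masks labels must be a 3-D array")
  }
  lab <- as.integer(labels)
  if (any(is.na(lab)) || any(lab < 0L) || any(lab > 5L)) {
    stop_("labels must be integers in 0..5")
  }
  labels <- array(lab, dim(labels))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop_("spacing must be 3 positive numbers (mm)")
  }
  counts <- tabulate(labels, nbins = 5L)
  if (any(counts == 0L)) {
    stop_("lobe %s has zero voxels", LOBE_NAMES[which(counts == 0L)[1]])
  }
  structure(list(labels = labels, spacing = spacing,
                 lobe_names = LOBE_NAMES),
            class = "lobar_masks")
}

#' @export
print.lobar_masks <- function(x, ...) {
  counts <- tabulate(x$labels, nbins = 5L)
  cat("<lobar_masks: ",
      paste(sprintf("%s=%d", LOBE_NAMES, counts), collapse = " "), ">\n",
      sep = "")
  invisible(x)
}

#' Per-lobe voxel counts
#' @param masks a [lobar_masks()] object.
#' @return named integer vector over the five lobes.
#' @export
lobe_voxel_counts <- function(masks) {
  stats::setNames(tabulate(masks$labels, nbins = 5L), LOBE_NAMES)
}

# Logical lung mask (union of the five lobes; no airway label exists).
lung_mask <- function(masks) masks$labels > 0L
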