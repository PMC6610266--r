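# Shared fixtures: small, fast phantom specs built in code.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 24L), ...)
}

tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(24L, 24L, 20L), ...)
}

# A hand-laid 5-lobe mask on a tiny grid: five disjoint slabs along z.
# Not anatomical; used where scores must be checkable by hand.
slab_masks <- function(nx = 6L, ny = 6L, nz = 10L, spacing = c(4, 4, 4)) {
  labels <- array(0L, c(nx, ny, nz))
  for (l in 1:5) labels[, , (2 * l - 1):(2 * l)] <- l
  lobar_masks(labels, spacing)
}

# Uniform-signal volume on the grid of a mask set.
uniform_vol <- function(masks, value = 1, role = "hpx_signal") {
  voxel_grid(array(value, dim(masks$labels)), masks$spacing, role)
}
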