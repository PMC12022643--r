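# Small, fast phantom configurations and analytic mask builders used across
# the test files.

# a compact 3-slice subject that quantifies in well under a second
small_params <- function(noise_sd = c(t1 = 0, lge = 0), lesion_spec = list(),
                         seed = 1L, ...) {
  phantom_params(grid_size = 72, n_slices = 3,
                 endo_radius = c(20, 18, 14), epi_radius = c(30, 28, 23),
                 noise_sd = noise_sd, lesion_spec = lesion_spec,
                 seed = seed, ...)
}

# study-sized base parameters for the paired-cohort generator (the solved
# per-subject geometry needs the full default grid)
cohort_base <- function(noise_sd = c(t1 = 0, lge = 0)) {
  phantom_params(noise_sd = noise_sd)
}

# concentric (optionally eccentric-endo) annulus contours on a square grid
annulus_contours <- function(r_endo, r_epi, grid = 96, spacing = 1,
                             endo_offset = c(0, 0), level = "mid",
                             anterior = NULL, inferior = NULL) {
  ctr <- (grid - 1) / 2
  g <- expand.grid(row = seq_len(grid) - 1, col = seq_len(grid) - 1)
  re <- sqrt((g$row - ctr - endo_offset[1])^2 + (g$col - ctr - endo_offset[2])^2)
  rp <- sqrt((g$row - ctr)^2 + (g$col - ctr)^2)
  endo <- matrix(re * spacing <= r_endo, grid, grid)
  epi <- matrix(rp * spacing <= r_epi, grid, grid)
  if (is.null(anterior)) anterior <- c(ctr + r_epi / spacing, ctr)
  if (is.null(inferior)) {
    # 240 deg of counterclockwise sweep from the anterior direction
    th <- atan2(anterior[2] - ctr, anterior[1] - ctr) + 240 * pi / 180
    inferior <- c(ctr + r_epi / spacing * cos(th), ctr + r_epi / spacing * sin(th))
  }
  slice_contours(endo, epi, anterior, inferior, level = level,
                 voxel_spacing = spacing)
}

# voxel-center radii of the TRUE voxels of a mask about the grid center
mask_radii <- function(mask, spacing = 1) {
  ctr <- (nrow(mask) - 1) / 2
  idx <- which(mask, arr.ind = TRUE)
  sqrt((idx[, 1] - 1 - ctr)^2 + (idx[, 2] - 1 - ctr)^2) * spacing
}
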