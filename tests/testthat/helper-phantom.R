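# Shared fixtures: small phantoms keep the unit tests fast; the acceptance
# suite uses the full-size defaults.

small_spec <- function(seed = 0L, pose = diag(4), skull = FALSE, snr = 25,
                       grid_dim = c(48L, 64L, 48L), ...) {
  phantom_spec(grid_dim = grid_dim, voxel_mm = 0.04,
               semi_axes = c(0.62, 0.95, 0.52), gm_thickness = 0.18,
               bulb_radius = 0.28, skull = skull, skull_gap = 0.04,
               skull_thickness = 0.06, snr = snr, pose = pose, seed = seed,
               ...)
}

dice <- function(a, b) {
  if (inherits(a, "mm_mask")) a <- a$data
  if (inherits(b, "mm_mask")) b <- b$data
  2 * sum(a & b) / (sum(a) + sum(b))
}

# brute-force rasterisation of a solid sphere (voxel centres, 0-based ijk)
rasterise_sphere <- function(dm, centre, radius) {
  g <- expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1), k = 0:(dm[3] - 1))
  arr <- (g$i - centre[1])^2 + (g$j - centre[2])^2 + (g$k - centre[3])^2 <=
    radius^2
  array(arr, dm)
}

# phantom-free tissue maps for QC tests
toy_tpms <- function(gm, wm, affine) {
  bg <- 1 - gm - wm
  tissue_probability_maps(list(GM = gm, WM = wm, BG = bg), affine)
}
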