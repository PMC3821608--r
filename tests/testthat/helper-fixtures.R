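# Shared fixtures: small, fast configurations used across test files.

# water-value FRAP scenario (noise off unless a test turns it on)
water_scenario <- function(D_true = 1.28e-6, noise_sigma = 0, ...) {
  bleach_scenario(D_true = D_true, omega = 50, noise_sigma = noise_sigma,
                  ...)
}

# thin all-culture column for 1D oxygen checks: nx = ny = 1
column_spec <- function(thickness, voxel = 2) {
  scaffold_spec(total_thickness = thickness, layer_height = thickness,
                pitch = voxel, alpha = 0, voxel_size = voxel)
}

column_grid <- function(thickness, voxel = 2) {
  build_scaffold(column_spec(thickness, voxel))
}

# small lattice scaffold for coupled-run tests (quarter domain 6 x 6 x nz)
small_lattice_spec <- function(alpha = 0.5, thickness = 300, pitch = 120,
                               voxel = 10, arrangement = "lattice") {
  scaffold_spec(total_thickness = thickness, layer_height = 50,
                pitch = pitch, alpha = alpha, arrangement = arrangement,
                voxel_size = voxel)
}

# uniform-density field on the culture voxels of a grid
uniform_rho <- function(grid, value) {
  rho <- array(0, dim = dim(grid$labels))
  rho[grid$labels == 0L] <- value
  rho
}
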