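# Shared fixtures, generated in code at test time.

fx_grid <- function(n = 64L, spacing = 2e-4) pa_grid(c(n, n), spacing)

# Odd-sized grid so the middle voxel center sits exactly at the origin.
fx_centered_grid <- function(n = 65L, spacing = 2e-4) pa_grid(c(n, n), spacing)

fx_acq <- function(n_samples = 512L, fs = 7.5e6, c0 = 1500) {
  pa_acquisition(sound_speed = c0, sampling_rate = fs, n_samples = n_samples)
}

# Single-voxel source at a voxel center (offset in voxels from the middle).
fx_point_phantom <- function(grid, offset_vox = c(0, 0), amplitude = 1) {
  ax <- grid_axes(grid)
  mid <- (grid$shape + 1) %/% 2
  ctr <- c(ax[[1]][mid[1] + offset_vox[1]], ax[[2]][mid[2] + offset_vox[2]])
  make_disk_phantom(grid, list(list(center = ctr,
                                    radius = min(grid$spacing) / 4,
                                    amplitude = amplitude)))
}

fx_point_data <- function(n_grid = 65L, n_elements = 32L,
                          offset_vox = c(0, 0), radius = 0.05,
                          n_samples = 512L) {
  grid <- fx_centered_grid(n_grid)
  geom <- make_ring_array(n_elements, radius)
  params <- fx_acq(n_samples)
  phantom <- fx_point_phantom(grid, offset_vox)
  list(grid = grid, geometry = geom, params = params, phantom = phantom,
       data = simulate_channel_data(phantom, geom, params))
}

# Small three-disk ring experiment configuration for run_all tests.
fx_small_config <- function(plan_seed = 11L) {
  list(
    grid = list(shape = c(64L, 64L), spacing = 4e-4),
    geometry = list(type = "ring", n_elements = 32L, radius = 0.05),
    acquisition = list(sound_speed = 1500, sampling_rate = 3.75e6,
                       n_samples = 256L),
    phantom = list(type = "disks", disks = list(
      list(center = c(-0.004, 0.003), radius = 0.0025, amplitude = 1),
      list(center = c(0.005, -0.002), radius = 0.0015, amplitude = 0.8))),
    prior = list(algo = "ubp", s = 6L, k = 15L, seed = plan_seed),
    risp = list(lambda_con = 0.2, lambda_reg = 0.8, learning_rate = 0.001,
                num_iters = 50L))
}

# Channel data with hand-set traces (for filter and DAS unit checks).
fx_manual_data <- function(traces, radius = 0.05, fs = 7.5e6, c0 = 1500) {
  geom <- make_ring_array(nrow(traces), radius)
  params <- pa_acquisition(sound_speed = c0, sampling_rate = fs,
                           n_samples = ncol(traces))
  risp:::new_channel_data(traces, geom, params)
}
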