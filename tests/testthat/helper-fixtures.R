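# Shared fixture builders; everything is generated in code.

# A small calibrated virtual rig: distorted optics + fitted map.
fixture_rig <- function(seed = 11, nx = 60, ny = 60, noise_sd = 0.3,
                        degree = 3) {
  optics <- random_optics(seed = seed, magnitude_px = 15,
                          noise_sd = noise_sd)
  bounds <- list(x = optics$voltage_bounds$x * 0.95,
                 y = optics$voltage_bounds$y * 0.95)
  obs <- acquire_raster(make_raster(nx, ny, bounds), optics,
                        seed = seed + 1)
  list(optics = optics, map = fit_map(obs, degree = degree), obs = obs,
       bounds = bounds)
}

# Single-part pose series from explicit vectors.
fixture_pose <- function(x, y, lik = rep(0.95, length(x)), fps = 30,
                         part = "left_hindpaw_mid",
                         frame_size = c(1100, 1100)) {
  pose_series(matrix(x, dimnames = list(NULL, part)),
              matrix(y, dimnames = list(NULL, part)),
              matrix(lik, dimnames = list(NULL, part)),
              fps = fps, frame_size = frame_size)
}

# Plain trajectory data.frame.
fixture_traj <- function(x, y, fps = 30) {
  data.frame(time = (seq_along(x) - 1) / fps, x = x, y = y)
}
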