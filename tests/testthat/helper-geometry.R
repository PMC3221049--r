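# Shared small fixtures, built in code.

# default desk-scale forward geometry
test_head <- function() head_model(sphere_radius = 90)

test_sensors <- function(n = 96, kind = "magnetometer")
  make_helmet_array(n, helmet_radius = 110, coverage_angle = 120, kind = kind)

# a small folded sheet, cached per session (geometry only depends on args)
local_cortex <- local({
  cache <- list()
  function(extent = 40, amplitude = 3, seed = 1) {
    key <- paste(extent, amplitude, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- make_synthetic_cortex(extent, fold_amplitude = amplitude,
                                             fold_wavelength = 25,
                                             target_spacing = 1, seed = seed)
    cache[[key]]
  }
})

# flat regular grid mesh in the z = z0 plane (nx x ny vertices, unit spacing)
flat_grid_mesh <- function(nx = 5, ny = 5, z0 = 0) {
  verts <- as.matrix(expand.grid(x = seq_len(nx) - (nx + 1) / 2,
                                 y = seq_len(ny) - (ny + 1) / 2))
  verts <- cbind(verts, z0)
  idx <- matrix(seq_len(nx * ny), nx, ny)
  tris <- list()
  for (j in seq_len(ny - 1)) {
    i <- seq_len(nx - 1)
    tris[[j]] <- rbind(cbind(idx[i, j], idx[i + 1, j], idx[i, j + 1]),
                       cbind(idx[i + 1, j], idx[i + 1, j + 1], idx[i, j + 1]))
  }
  trimesh(verts, do.call(rbind, tris))
}

expect_unit_rows <- function(m, tol = 1e-9) {
  expect_true(all(abs(sqrt(rowSums(m^2)) - 1) < tol))
}
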