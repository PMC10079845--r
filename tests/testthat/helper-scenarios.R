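# shared fixtures, built once per test run
.fixture_env <- new.env()

fixture_scenario <- function(name, ...) {
  key <- paste(name, ..., sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_scenario(name, ...)
  }
  .fixture_env[[key]]
}

# single-bin monochromatic spectrum on the standard grid
mono_spectrum <- function(energy_kev, flux = 1e10) {
  edges <- seq(1, 400, by = 0.5)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  f <- numeric(length(ctr))
  f[which.min(abs(ctr - energy_kev))] <- flux
  xray_spectrum(edges, f)
}

# brute-force ray-marching oracle for path lengths through the geometry
march_path_lengths <- function(origin, direction, geometry, step = 5e-4,
                               t_end = 20) {
  ts <- seq(step / 2, t_end, by = step)
  px <- origin[1] + ts * direction[1]
  py <- origin[2] + ts * direction[2]
  pz <- origin[3] + ts * direction[3]
  rc <- rhizodose:::.root_center(geometry)
  in_soil <- px^2 + py^2 < geometry$soil_radius^2 &
    abs(pz) < geometry$soil_height / 2
  in_root <- (px - rc[1])^2 + (py - rc[2])^2 < geometry$root_radius^2 &
    abs(pz) < geometry$root_height / 2 & in_soil
  list(soil = sum(in_soil & !in_root) * step,
       root = sum(in_root) * step)
}
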