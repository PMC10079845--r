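#' Synthetic soil compositions
#'
#' `"oxisol_default"` returns the packaged nine-element Oxisol-like
#' composition (see [load_default_soil()]). `"randomized"` jitters the minor
#' constituents around the default (deterministically for a given seed)
#' while keeping the combined O+Si+Al solid mass fraction at or above 0.88
#' and all phase parameters fixed.
#'
#' @param profile `"oxisol_default"` or `"randomized"`.
#' @param seed RNG seed used for the randomized profile.
#' @return a [soil_spec()].
#' @export
make_soil <- function(profile = c("oxisol_default", "randomized"),
                      seed = 1) {
  profile <- match.arg(profile)
  base <- load_default_soil()
  if (profile == "oxisol_default") return(base)
  set.seed(seed)
  comp <- base$solid_fractions
  minor <- c("Fe", "C", "Ti", "K", "Ca", "H")
  comp[minor] <- comp[minor] * runif(length(minor), 0.8, 1.2)
  major <- c("O", "Si", "Al")
  comp[major] <- comp[major] * (1 - sum(comp[minor])) / sum(comp[major])
  stopifnot(sum(comp[major]) >= 0.88)
  soil_spec(comp / sum(comp))
}

# MOGNO-A beamline constants: vacuum path 21.481 m of the 22.915 m
# source-to-sample distance; the rest is air, behind a 0.2 mm diamond window
.MOGNO_A_AIR_MM <- (22.915 - 21.481) * 1000
.MOGNO_A_TABLE <- list(
  E1R1 = list(si = 0.36, nproj = 256, ma = 10, tpp = 0.16,
              full_s = 41.35, start = 180),
  E2R1 = list(si = 2.45, nproj = 256, ma = 10, tpp = 0.48,
              full_s = 123, start = 330),
  E2R2 = list(si = 2.45, nproj = 1024, ma = 10, tpp = 0.57,
              full_s = 583.8, start = 150),
  E3R1 = list(si = 2.45, nproj = 512, ma = 40, tpp = 0.015,
              full_s = 7.68, start = 135),
  E3R2 = list(si = 2.45, nproj = 512, ma = 40, tpp = 0.015,
              full_s = 7.68, start = 240))
.MOGNO_B_ENERGY <- list(
  low = list(peak = 22, flux = 6.01e9, si = 0.71),
  mid = list(peak = 39, flux = 5.01e8, si = 7.07),
  high = list(peak = 67.5, flux = 1.47e8, si = 7.07))
# position letter -> (sample diameter mm, nominal FOV mm)
.MOGNO_B_POSITION <- list(
  a = list(diameter = 2.9, fov = 0.0775),
  b = list(diameter = 2.9, fov = 2.8985),
  c = list(diameter = 14, fov = 14),
  d = list(diameter = 40, fov = 40))

# base bending-magnet spectrum at the sample (diamond window + air path),
# cached because the universal-function quadrature is the expensive part
.mogno_a_spectrum <- function(si_mm) {
  if (is.null(.rhizo_cache$mogno_a_base)) {
    bc <- bending_magnet_spectrum(critical_energy = 0.665 * 3.0^2 * 3.2,
                                  total_flux = 4.61e13)
    .rhizo_cache$mogno_a_base <- attenuate(bc, filter_stack(
      beam_filter(mat_diamond(), 0.2),
      beam_filter(mat_air(), .MOGNO_A_AIR_MM)))
  }
  sp <- .rhizo_cache$mogno_a_base
  if (si_mm > 0) sp <- attenuate(sp, beam_filter(mat_silicon(), si_mm))
  sp
}

# quasi-monochromatic mirror output, Si-filtered, rescaled to the at-sample
# flux (the quoted fluxes count all photons reaching the sample holder)
.mogno_b_spectrum <- function(energy) {
  en <- .MOGNO_B_ENERGY[[energy]]
  sp <- quasi_mono_spectrum(peak = en$peak, total_flux = en$flux)
  sp <- attenuate(sp, beam_filter(mat_silicon(), en$si))
  sp$flux <- sp$flux * en$flux / sum(sp$flux)
  sp$provenance <- c(sp$provenance,
                     sprintf("rescaled to %.3g photons/s/mA at sample",
                             en$flux))
  sp
}

#' Packaged imaging scenarios
#'
#' Builds the full configuration (spectrum, filter stack, sample geometry,
#' beam model and, for the tomographic experiments, the scan protocol) for
#' the packaged scenario names:
#'
#' * `E1R1`, `E2R1`, `E2R2`, `E3R1`, `E3R2` -- polychromatic bending-magnet
#'   experiments: 2.9 mm soil sample, root (0.6 mm diameter) at 1 mm radial
#'   offset, 180-degree clockwise scans.
#' * `mognoB_<pos>_<energy>` -- quasi-monochromatic cone-beam comparisons
#'   with a centered root; `<pos>` is `a` (2.9 mm sample, 0.077 mm FOV),
#'   `b` (2.9 mm, 2.9 mm FOV), `c` (14 mm, 14 mm FOV) or `d` (40 mm, 40 mm
#'   FOV); `<energy>` is `low` (22 keV peak), `mid` (39 keV) or `high`
#'   (67.5 keV).
#'
#' @param name scenario name.
#' @param fov_mm optional FOV override for the cone-beam scenarios (the
#'   focus-to-sample distance is set to `fov_mm / 3.1 mrad`); e.g. pair a
#'   40 mm sample with the 0.077 mm FOV.
#' @param soil a [soil_spec()]; default the packaged soil.
#' @return an object of class `rhizo_scenario`.
#' @export
make_scenario <- function(name, fov_mm = NULL, soil = load_default_soil()) {
  soil_mat <- bulk_soil_material(soil)
  if (name %in% names(.MOGNO_A_TABLE)) {
    p <- .MOGNO_A_TABLE[[name]]
    sc <- list(
      name = name,
      spectrum = .mogno_a_spectrum(p$si),
      geometry = sample_geometry(theta = p$start,
                                 soil_material = soil_mat),
      beam = mogno_a_beam(),
      protocol = scan_protocol(p$nproj, p$ma, p$tpp, p$full_s,
                               start_angle_deg = p$start),
      meta = list(source = "polychromatic", si_filter_mm = p$si))
    return(structure(sc, class = "rhizo_scenario"))
  }
  m <- regmatches(name, regexec("^mognoB_([abcd])_(low|mid|high)$", name))[[1]]
  if (!length(m)) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(c(names(.MOGNO_A_TABLE),
                 outer(paste0("mognoB_", names(.MOGNO_B_POSITION)),
                       names(.MOGNO_B_ENERGY), paste, sep = "_")),
               collapse = ", "))
  }
  pos <- .MOGNO_B_POSITION[[m[2]]]
  fov <- if (is.null(fov_mm)) pos$fov else fov_mm
  sc <- list(
    name = name,
    spectrum = .mogno_b_spectrum(m[3]),
    geometry = sample_geometry(soil_radius = pos$diameter / 2,
                               soil_height = max(5.25, pos$diameter),
                               root_offset = 0,
                               soil_material = soil_mat),
    beam = mogno_b_beam(distance_m = fov / 3.1),
    protocol = NULL,
    meta = list(source = paste0("quasi-monochromatic (", m[3], ")"),
                si_filter_mm = .MOGNO_B_ENERGY[[m[3]]]$si))
  structure(sc, class = "rhizo_scenario")
}

#' @export
print.rhizo_scenario <- function(x, ...) {
  cat("<rhizo_scenario> ", x$name, " (", x$meta$source, ", ",
      x$meta$si_filter_mm, " mm Si)\n", sep = "")
  print(x$spectrum)
  print(x$geometry)
  print(x$beam)
  if (!is.null(x$protocol)) print(x$protocol)
  invisible(x)
}

#' Scenario YAML IO
#'
#' Writes a scenario's defining parameters (name, FOV, soil) to YAML and
#' rebuilds it with [make_scenario()].
#'
#' @param scenario a [make_scenario()] object.
#' @param path file path.
#' @return `read_scenario` returns the rebuilt scenario; `write_scenario`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(list(
    name = scenario$name,
    fov_mm = scenario$beam$fov_mm,
    source = scenario$meta$source,
    si_filter_mm = scenario$meta$si_filter_mm,
    sample_diameter_mm = 2 * scenario$geometry$soil_radius), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (grepl("^mognoB_", y$name)) {
    make_scenario(y$name, fov_mm = y$fov_mm)
  } else {
    make_scenario(y$name)
  }
}

#' Configuration for the synthetic growth-series generator
#'
#' Defaults emulate the study conditions: a healthy wheat seminal root
#' grows 0.5--0.8 mm/h; repeated tomographic scans each deposit a
#' kilogray-scale dose; the growth rate declines linearly with cumulative
#' dose until it arrests.
#'
#' @param baseline_mm_h baseline growth rate; `NULL` draws uniformly from
#'   0.5--0.8 mm/h.
#' @param sensitivity_mm_h_per_gy decline of growth rate per unit
#'   cumulative dose (mm/h per Gy).
#' @param noise_sd_mm_h Gaussian rate noise (truncated so rates stay
#'   non-negative).
#' @param dose_per_tp_gy dose deposited by each scan, Gy (scalar or one per
#'   scan).
#' @param n_tp number of timepoints (masks); `n_tp - 1` growth intervals.
#' @param interval_h time between timepoints, hours.
#' @param voxel_mm voxel size of the generated masks.
#' @param grid mask grid dimensions.
#' @param root_radius_mm radius of the synthetic root cylinder.
#' @param initial_length_mm root length at the first timepoint.
#' @param seed RNG seed.
#' @return a list of class `growth_sim_config`.
#' @export
growth_sim_config <- function(baseline_mm_h = NULL,
                              sensitivity_mm_h_per_gy = 2e-5,
                              noise_sd_mm_h = 0.02,
                              dose_per_tp_gy = 5700,
                              n_tp = 5, interval_h = 1,
                              voxel_mm = 0.00288,
                              grid = c(40, 40, 1500),
                              root_radius_mm = 0.05,
                              initial_length_mm = 0.5,
                              seed = 1) {
  if (!is.null(baseline_mm_h) && baseline_mm_h <= 0) {
    stop("baseline must be > 0")
  }
  if (noise_sd_mm_h < 0) stop("noise sd must be >= 0")
  structure(list(baseline_mm_h = baseline_mm_h,
                 sensitivity_mm_h_per_gy = sensitivity_mm_h_per_gy,
                 noise_sd_mm_h = noise_sd_mm_h,
                 dose_per_tp_gy = dose_per_tp_gy, n_tp = n_tp,
                 interval_h = interval_h, voxel_mm = voxel_mm, grid = grid,
                 root_radius_mm = root_radius_mm,
                 initial_length_mm = initial_length_mm, seed = seed),
            class = "growth_sim_config")
}

#' Simulate a root-growth mask series with a linear dose response
#'
#' Growth rate in interval k is
#' `max(0, baseline - sensitivity * cumulative_dose(k) + noise)`, where
#' `cumulative_dose(k)` is the dose accumulated over the first k scans.
#' Masks are voxelised cylinders advanced along the growth axis
#' accordingly. The generator returns the ground truth for parameter
#' recovery experiments.
#'
#' @param config a [growth_sim_config()].
#' @param masks logical; generate the voxel masks (set `FALSE` for fast
#'   rate-level simulations, e.g. many-seed recovery studies).
#' @return list with `series` (a [root_mask_series()] or `NULL`),
#'   `rates_mm_h` (observed rates), `rates_true_mm_h` (noise-free),
#'   `cum_dose_gy`, `baseline_mm_h` and `config`.
#' @export
simulate_growth_series <- function(config = growth_sim_config(),
                                   masks = TRUE) {
  stopifnot(inherits(config, "growth_sim_config"))
  set.seed(config$seed)
  baseline <- if (is.null(config$baseline_mm_h)) {
    runif(1, 0.5, 0.8)
  } else config$baseline_mm_h
  n_int <- config$n_tp - 1
  dose_tp <- rep(config$dose_per_tp_gy, length.out = config$n_tp)
  cum <- cumsum(dose_tp)[seq_len(n_int)]
  true <- pmax(0, baseline - config$sensitivity_mm_h_per_gy * cum)
  noise <- rnorm(n_int, 0, config$noise_sd_mm_h)
  rates <- pmax(0, true + noise)
  series <- NULL
  if (masks) {
    g <- config$grid
    cx <- (g[1] + 1) / 2; cy <- (g[2] + 1) / 2
    rvox <- config$root_radius_mm / config$voxel_mm
    disc <- outer(seq_len(g[1]) - cx, seq_len(g[2]) - cy,
                  function(i, j) i^2 + j^2) <= rvox^2
    lengths_mm <- config$initial_length_mm +
      c(0, cumsum(rates * config$interval_h))
    ms <- lapply(lengths_mm, function(L) {
      nz <- min(g[3], max(1, round(L / config$voxel_mm)))
      m <- array(FALSE, g)
      m[, , seq_len(nz)] <- disc
      m
    })
    series <- root_mask_series(ms, config$voxel_mm,
                               times_h = (seq_len(config$n_tp) - 1) *
                                 config$interval_h)
  }
  list(series = series, rates_mm_h = rates, rates_true_mm_h = true,
       cum_dose_gy = cum, baseline_mm_h = baseline, config = config)
}

#' Write a directory of plain-text fixtures
#'
#' Emits the packaged soil composition (CSV), the filtered polychromatic
#' spectrum (two-column text), every packaged scenario (YAML) and one small
#' example mask (CSV voxel list).
#'
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_soil_spec(load_default_soil(), file.path(dir, "soil_default.csv"))
  sc <- make_scenario("E1R1")
  write_spectrum(sc$spectrum, file.path(dir, "spectrum_E1.txt"))
  for (nm in c(names(.MOGNO_A_TABLE), "mognoB_b_high", "mognoB_a_high")) {
    s <- if (nm == "mognoB_a_high") {
      make_scenario("mognoB_a_high")
    } else if (grepl("^mognoB", nm)) make_scenario(nm) else make_scenario(nm)
    write_scenario(s, file.path(dir, paste0(nm, ".yaml")))
  }
  sim <- simulate_growth_series(growth_sim_config(
    grid = c(10, 10, 120), root_radius_mm = 0.01, initial_length_mm = 0.05,
    n_tp = 3, dose_per_tp_gy = 1000))
  write_root_mask(sim$series$masks[[1]], file.path(dir, "mask_tp1.csv"),
                  sim$config$voxel_mm)
  invisible(dir)
}
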