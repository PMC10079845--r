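#' Photon fluence rate at the sample plane
#'
#' Divides each spectrum bin by the illuminated area of the beam model:
#' the FOV area for a focused cone beam, or the divergence footprint
#' `(divergence * distance)^2` for an unfocused slit-limited beam. Total
#' flux is conserved: fluence times illuminated area returns the spectrum.
#'
#' @param spectrum an [xray_spectrum()].
#' @param beam a [beam_model()].
#' @return per-bin fluence rate, photons/mm^2/s/mA.
#' @export
fluence_rate <- function(spectrum, beam) {
  stopifnot(inherits(spectrum, "xray_spectrum"),
            inherits(beam, "beam_model"))
  area <- .illuminated_area_mm2(beam)
  if (area <= 0) stop("illuminated area must be > 0")
  spectrum$flux / area
}

# photons/mm2 -> photons/cm2, keV -> J, /g -> /kg combined
.KERMA_CONST <- 100 * .KEV_TO_J * 1000

#' Unattenuated kerma rate in a material
#'
#' Closed-form collision kerma rate for the raw beam impinging on a thin
#' target with no upstream absorber:
#' `sum_b phi_b E_b (mu_en/rho)(E_b)` converted to Gy/s/mA.
#'
#' @param spectrum an [xray_spectrum()].
#' @param beam a [beam_model()].
#' @param material the target [material_mixture()].
#' @return dose rate, Gy/s/mA.
#' @export
kerma_rate_unattenuated <- function(spectrum, beam, material) {
  ctr <- bin_centers(spectrum)
  phi <- fluence_rate(spectrum, beam)
  occ <- phi > 0
  men <- mass_coefficient(material, ctr[occ], "energy_absorption")
  sum(phi[occ] * ctr[occ] * men) * .KERMA_CONST
}

# upstream (against +x beam) path lengths in mm for points (x, y) inside the
# soil; vectorised; returns list(soil, root)
.upstream_lengths <- function(x, y, geometry) {
  rs <- geometry$soil_radius
  x_in <- -sqrt(pmax(rs^2 - y^2, 0))
  total <- x - x_in
  rc <- .root_center(geometry)
  dy <- y - rc[2]
  rr <- geometry$root_radius
  inside <- abs(dy) < rr & geometry$root_radius > 0
  rx <- sqrt(pmax(rr^2 - dy^2, 0))
  root_up <- ifelse(inside,
                    pmax(0, pmin(x, rc[1] + rx) - (rc[1] - rx)), 0)
  list(soil = pmax(total - root_up, 0), root = root_up)
}

# kerma dose rate (Gy/s/mA) at sample points given upstream lengths (mm)
# through soil and root; mu_en of the target material at the points
.kerma_at_points <- function(spectrum, beam, geometry, lsoil, lroot,
                             target_material,
                             absorption = "energy_absorption") {
  ctr <- bin_centers(spectrum)
  phi <- fluence_rate(spectrum, beam)
  occ <- which(phi > 0)
  if (!length(occ)) return(numeric(length(lsoil)))
  e <- ctr[occ]
  mus <- .mu_linear(geometry$soil_material, e) / 10    # 1/mm
  mur <- .mu_linear(geometry$root_material, e) / 10
  men <- mass_coefficient(target_material, e, absorption)
  w <- phi[occ] * e * men * .KERMA_CONST
  att <- exp(-(outer(mus, lsoil) + outer(mur, lroot)))
  drop(crossprod(att, w))
}

#' Deterministic kerma dose rate in a region
#'
#' Primary-beam attenuation plus local energy absorption (collision kerma):
#' for sample points x in the region,
#' `rate(x) = sum_b phi_b exp(-sum_j mu_j l_j(x)) E_b (mu_en/rho)(E_b)`,
#' volume-averaged over the region by deterministic quadrature. Scattered
#' photons are not transported (see the Monte Carlo engine for the
#' scatter-aware estimate).
#'
#' @param spectrum an [xray_spectrum()].
#' @param geometry a [sample_geometry()].
#' @param beam a [beam_model()]; its `beamlet_mm` defines the illuminated
#'   root segment.
#' @param region `"root_segment"` or `"soil_increment"`.
#' @param increment radial increment index (1 = innermost) when
#'   `region = "soil_increment"`; increments are `dr_mm` thick.
#' @param dr_mm radial increment thickness, mm.
#' @param n_y,n_x quadrature points across the beamlet and along the chord.
#' @param absorption coefficient governing local energy deposition:
#'   `"energy_absorption"` (collision kerma, default) or `"total"` (every
#'   interaction absorbs fully; the closed form matched by the Monte Carlo
#'   engine on a purely absorbing toy material).
#' @return dose rate, Gy/s/mA.
#' @export
kerma_dose_rate <- function(spectrum, geometry, beam,
                            region = c("root_segment", "soil_increment"),
                            increment = 1, dr_mm = 0.29,
                            n_y = 15, n_x = 21,
                            absorption = c("energy_absorption", "total")) {
  region <- match.arg(region)
  absorption <- match.arg(absorption)
  stopifnot(inherits(geometry, "sample_geometry"))
  if (region == "root_segment") {
    rc <- .root_center(geometry)
    w <- beam$beamlet_mm
    if (abs(rc[2]) - w / 2 > beam$fov_mm / 2) {
      warning("root segment lies outside the beam; dose is zero")
      return(0)
    }
    rr <- geometry$root_radius
    ys <- rc[2] + (seq_len(n_y) - 0.5) / n_y * w - w / 2
    ys <- ys[abs(ys - rc[2]) < rr]
    pts_x <- c(); pts_y <- c(); wt <- c()
    for (y in ys) {
      rx <- sqrt(rr^2 - (y - rc[2])^2)
      xs <- rc[1] + (2 * (seq_len(n_x) - 0.5) / n_x - 1) * rx
      pts_x <- c(pts_x, xs)
      pts_y <- c(pts_y, rep(y, n_x))
      wt <- c(wt, rep(2 * rx / n_x, n_x))
    }
    target <- geometry$root_material
  } else {
    r_lo <- (increment - 1) * dr_mm
    r_hi <- increment * dr_mm
    if (r_hi > geometry$soil_radius + 1e-9) {
      stop("increment extends beyond the soil radius")
    }
    # area-weighted polar grid over the annulus (no root in this analysis)
    nr <- 8; nphi <- 72
    rs <- sqrt(seq(r_lo^2, r_hi^2, length.out = nr + 1))
    rm <- (rs[-1] + rs[-(nr + 1)]) / 2
    phis <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
    gr <- expand.grid(r = rm, phi = phis)
    pts_x <- -gr$r * cos(gr$phi)
    pts_y <- gr$r * sin(gr$phi)
    wt <- rep(rs[-1]^2 - rs[-(nr + 1)]^2, nphi)
    target <- geometry$soil_material
  }
  up <- .upstream_lengths(pts_x, pts_y, geometry)
  rate <- .kerma_at_points(spectrum, beam, geometry, up$soil, up$root,
                           target, absorption)
  sum(rate * wt) / sum(wt)
}

#' Transport configuration for the Monte Carlo engine
#'
#' @param n_primaries number of source photons.
#' @param n_batches number of statistically independent batches used for
#'   the uncertainty estimate.
#' @param cutoff_kev photon cutoff energy; photons falling below it deposit
#'   their remaining energy locally.
#' @param coherent logical; transport coherent (Rayleigh) scattering.
#' @param photoelectric_only logical; treat every interaction as full local
#'   absorption (useful to cross-validate against the kerma engine on an
#'   absorbing-only toy material).
#' @param segment_volume_cm3 normalisation volume for the root-segment
#'   region tally; `NULL` uses the analytic beamlet-root intersection
#'   volume.
#' @return an object of class `transport_config`.
#' @export
transport_config <- function(n_primaries = 1e5, n_batches = 10,
                             cutoff_kev = 1, coherent = TRUE,
                             photoelectric_only = FALSE,
                             segment_volume_cm3 = NULL) {
  if (n_primaries < 1) stop("n_primaries must be >= 1")
  if (cutoff_kev <= 0) stop("cutoff must be positive")
  structure(list(n_primaries = as.integer(n_primaries),
                 n_batches = as.integer(n_batches),
                 cutoff_kev = cutoff_kev, coherent = coherent,
                 photoelectric_only = photoelectric_only,
                 segment_volume_cm3 = segment_volume_cm3),
            class = "transport_config")
}

#' Convert a per-primary dose tally to a dose rate
#'
#' `Gy/s/mA = tally[GeV/g/primary] * 1.602176462e-7 * flux[photons/s/mA]`.
#'
#' @param tally_gev_per_g dose tally, GeV/g per primary.
#' @param flux photon rate represented by one primary's worth of
#'   normalisation, photons/s/mA.
#' @return dose rate, Gy/s/mA.
#' @export
dose_conversion <- function(tally_gev_per_g, flux) {
  if (any(tally_gev_per_g < 0) || any(flux < 0)) {
    stop("inputs must be non-negative")
  }
  tally_gev_per_g * .GEV_PER_G_TO_GY * flux
}

# analytic volume of the beamlet-root intersection, cm^3
.segment_volume_cm3 <- function(geometry, beamlet_mm) {
  rr <- geometry$root_radius
  if (rr <= 0) return(Inf)   # no root: segment dose is identically zero
  a <- min(beamlet_mm / 2, rr)
  area <- 2 * (a * sqrt(rr^2 - a^2) + rr^2 * asin(a / rr))
  area * beamlet_mm / 1000        # mm^3 -> cm^3
}

#' Monte Carlo photon transport
#'
#' Analog photon transport through the soil/root geometry with Woodcock
#' (delta) tracking: photoelectric absorption (full local deposition),
#' incoherent scattering with Klein--Nishina energy/angle sampling (the
#' recoil electron's energy is deposited locally), and coherent scattering
#' (direction resampled against a screened form factor, no deposition).
#' Secondary electrons are not transported (kerma approximation). The air
#' around and inside the sample is treated as vacuum (its optical depth on
#' the mm scale is below 1e-4).
#'
#' Use [set.seed()] before calling for reproducible tallies.
#'
#' @param spectrum an [xray_spectrum()].
#' @param geometry a [sample_geometry()].
#' @param beam a [beam_model()]; the simulated beam cross-section is the
#'   beamlet centred on the root segment (or on the axis if
#'   `cross_center = "axis"`).
#' @param config a [transport_config()].
#' @param cross_mm edge of the simulated (square) beam cross-section;
#'   defaults to the beamlet. Set it to the beam FOV (with
#'   `cross_center = "axis"`) to illuminate the whole sample and capture the
#'   full scatter bath converging on the segment, at the cost of fewer
#'   primaries through the segment column.
#' @param cross_center `"root"` or `"axis"`.
#' @param n_azimuth if positive, also score a scatter-aware dose-to-water
#'   map over the soil shells with a Woodcock collision estimator, binned
#'   into this many azimuth bins (relative to the beam; 0 faces the
#'   incoming beam). Returned as `shell_water_rate`.
#' @param shell_edges radial edges (mm) of the concentric soil tally
#'   shells.
#' @return an object of class `dose_tally` with per-region dose rates
#'   (Gy/s/mA), per-primary tallies (GeV/g), relative statistical
#'   uncertainties, the scatter fractions of the segment and whole-root
#'   doses (the fraction deposited by photons that had already scattered at
#'   least once), and energy bookkeeping (emitted / deposited / escaped,
#'   keV per batch).
#' @export
mc_run <- function(spectrum, geometry, beam, config = transport_config(),
                   cross_mm = beam$beamlet_mm,
                   cross_center = c("root", "axis"),
                   n_azimuth = 0,
                   shell_edges = seq(0, by = 0.29, length.out = 5)) {
  cross_center <- match.arg(cross_center)
  stopifnot(inherits(spectrum, "xray_spectrum"),
            inherits(geometry, "sample_geometry"),
            inherits(config, "transport_config"))
  ctr <- bin_centers(spectrum)
  de <- diff(spectrum$edges)
  if (max(abs(de - de[1])) > 1e-9) stop("mc_run needs a uniform energy grid")
  rc <- .root_center(geometry)
  center_y <- if (cross_center == "root") rc[2] else 0

  # fine lookup grid for the transport coefficients (log-log interpolation
  # happens here, once; the engine interpolates linearly on this grid)
  efine <- seq(spectrum$edges[1], spectrum$edges[length(spectrum$edges)],
               by = 0.1)
  mats <- list(geometry$soil_material, geometry$root_material)
  comp <- function(m, kind) mass_coefficient(m, efine, kind) * m$density / 10
  mu_pe <- sapply(mats, comp, kind = "photoelectric")
  mu_inc <- sapply(mats, comp, kind = "incoherent")
  mu_coh <- sapply(mats, comp, kind = "coherent")
  # keep the summed partials exactly on the interpolated total attenuation
  # (the partials are interpolated separately, so their sum drifts from the
  # total between table nodes by a few tenths of a percent otherwise)
  scale <- sapply(mats, comp, kind = "total") / (mu_pe + mu_inc + mu_coh)
  mu_pe <- mu_pe * scale; mu_inc <- mu_inc * scale; mu_coh <- mu_coh * scale
  if (!config$coherent) mu_coh[] <- 0
  if (config$photoelectric_only) {
    mu_pe <- mu_pe + mu_inc + mu_coh
    mu_inc[] <- 0; mu_coh[] <- 0
  }
  # effective Z for the coherent form-factor screening, per material
  zeff <- vapply(mats, function(m) {
    tabs <- .element_tables()
    zs <- vapply(names(m$composition), function(s) tabs[[s]]$Z, numeric(1))
    sum(m$composition * zs^2) / sum(m$composition * zs)
  }, numeric(1))
  hbarc <- 1.973269804e-8
  scr <- 0.885 * 5.29177210903e-9 * zeff^(-1 / 3) / hbarc   # 1/keV

  # source photons carry the bin-center energies (the spectrum is a
  # histogram; the kerma engine uses the same discretisation)
  cdf <- cumsum(spectrum$flux) / sum(spectrum$flux)
  out <- mc_transport_cpp(
    e0 = efine[1], de = 0.1,
    mu_pe = mu_pe, mu_inc = mu_inc, mu_coh = mu_coh,
    src_cdf = cdf, src_lo = ctr, src_hi = ctr,
    soil_r = geometry$soil_radius, soil_hz = geometry$soil_height / 2,
    root_x = rc[1], root_y = rc[2], root_r = geometry$root_radius,
    root_hz = geometry$root_height / 2,
    cross_y = center_y, cross_z = 0, cross_half = cross_mm / 2,
    seg_y = rc[2], seg_z = 0, seg_half = beam$beamlet_mm / 2,
    shell_edges = shell_edges,
    scr = scr,
    men_water = mass_coefficient(mat_water(), efine, "energy_absorption"),
    n_azimuth = n_azimuth,
    cutoff = config$cutoff_kev,
    n_primaries = config$n_primaries, n_batches = config$n_batches)
  res <- out$tallies
  colnames(res) <- c("segment", "segment_scatter", "root", "root_scatter",
                     paste0("shell", 1:4), "deposited", "escaped", "emitted")

  vol_seg <- if (is.null(config$segment_volume_cm3)) {
    .segment_volume_cm3(geometry, beam$beamlet_mm)
  } else config$segment_volume_cm3
  fl <- fluence_rate(spectrum, beam)           # photons/mm^2/s/mA
  flux_cross <- sum(fl) * cross_mm^2           # photons/s/mA in the beamlet

  # the C++ engine runs n_primaries %/% n_batches histories per batch
  per_batch_primaries <- max(1, config$n_primaries %/% config$n_batches)
  n_run <- per_batch_primaries * config$n_batches
  seg_gev <- res[, "segment"] * 1e-6 /
    (vol_seg * geometry$root_material$density) / per_batch_primaries
  seg_rate <- dose_conversion(seg_gev, flux_cross)
  shell_rates <- matrix(NA_real_, config$n_batches, 4)
  zs <- min(beam$beamlet_mm, geometry$soil_height)
  for (i in 1:4) {
    vol <- pi * (shell_edges[i + 1]^2 - shell_edges[i]^2) * zs / 1000 # cm^3
    shell_gev <- res[, paste0("shell", i)] * 1e-6 /
      (vol * geometry$soil_material$density) / per_batch_primaries
    shell_rates[, i] <- dose_conversion(shell_gev, flux_cross)
  }
  shell_water <- NULL
  if (n_azimuth > 0) {
    nshell <- length(shell_edges) - 1
    tot <- matrix(rowSums(out$kerma_water), nrow = n_azimuth)  # keV cm^3/g
    vols <- pi * diff(shell_edges^2) / n_azimuth * zs / 1000   # cm^3
    shell_water <- sweep(tot, 2, vols, "/") / n_run *
      flux_cross * .KEV_TO_J * 1000                            # Gy/s/mA
  }
  mstat <- function(x) {
    m <- mean(x)
    list(mean = m,
         rel_unc = if (m > 0) sd(x) / sqrt(length(x)) / m else NA_real_)
  }
  seg <- mstat(seg_rate)
  structure(list(
    segment_rate = seg$mean,
    segment_rel_unc = seg$rel_unc,
    segment_gev_per_g = mean(seg_gev),
    segment_volume_cm3 = vol_seg,
    scatter_fraction = sum(res[, "segment_scatter"]) /
      max(sum(res[, "segment"]), .Machine$double.xmin),
    root_scatter_fraction = sum(res[, "root_scatter"]) /
      max(sum(res[, "root"]), .Machine$double.xmin),
    shell_rates = colMeans(shell_rates),
    shell_rel_unc = apply(shell_rates, 2, function(x)
      if (mean(x) > 0) sd(x) / sqrt(length(x)) / mean(x) else NA_real_),
    shell_water_rate = shell_water,
    energy_keV = res[, c("deposited", "escaped", "emitted")],
    n_primaries = config$n_primaries,
    n_batches = config$n_batches,
    flux_cross = flux_cross),
    class = "dose_tally")
}

#' @export
print.dose_tally <- function(x, ...) {
  cat("<dose_tally> ", format(x$n_primaries, big.mark = ","),
      " primaries in ", x$n_batches, " batches\n", sep = "")
  cat(sprintf("  root segment: %.4g Gy/s/mA (rel. unc. %.2g)\n",
              x$segment_rate, x$segment_rel_unc))
  cat(sprintf("  scatter fraction of segment dose: %.3f\n",
              x$scatter_fraction))
  invisible(x)
}

#' Write region tallies to CSV
#'
#' @param tally a `dose_tally` from [mc_run()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dose_tally <- function(tally, path) {
  d <- data.frame(
    region = c("root_segment", paste0("soil_shell_", 1:4)),
    dose_rate_gy_s_ma = c(tally$segment_rate, tally$shell_rates),
    rel_uncertainty = c(tally$segment_rel_unc, tally$shell_rel_unc))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
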