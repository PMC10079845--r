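#' Construct an X-ray spectrum object
#'
#' A spectrum is a binned photon flux: strictly increasing bin edges (keV)
#' and a non-negative flux per bin (photons/s/mA integrated over the beam
#' aperture), plus a provenance trail (source description and filters
#' applied).
#'
#' @param edges bin edges, keV, strictly increasing (length n+1).
#' @param flux photons/s/mA per bin (length n), all >= 0.
#' @param provenance character vector describing how the spectrum was made.
#' @return an object of class `xray_spectrum`.
#' @export
xray_spectrum <- function(edges, flux, provenance = character()) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (length(flux) != length(edges) - 1) {
    stop("flux must have one value per bin")
  }
  if (any(flux < 0)) stop("flux must be non-negative")
  structure(list(edges = edges, flux = flux, provenance = provenance),
            class = "xray_spectrum")
}

#' @export
print.xray_spectrum <- function(x, ...) {
  s <- spectrum_stats(x)
  cat("<xray_spectrum> ", length(x$flux), " bins, ",
      format(x$edges[1]), "-", format(x$edges[length(x$edges)]), " keV\n",
      "  total ", format(s$total, digits = 4), " photons/s/mA, E_p ",
      format(s$e_peak, digits = 4), " keV, E_m ",
      format(s$e_mean, digits = 4), " keV\n", sep = "")
  for (p in x$provenance) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' Bin centers of a spectrum
#' @param spectrum an [xray_spectrum()].
#' @return numeric vector of bin-center energies, keV.
#' @export
bin_centers <- function(spectrum) {
  e <- spectrum$edges
  (e[-1] + e[-length(e)]) / 2
}

# universal bending-magnet function G1(y) = y * int_y^Inf K_{5/3}(x) dx,
# evaluated by adaptive quadrature and cached on a log grid
.g1_universal <- function(y) {
  if (is.null(.rhizo_cache$g1_grid)) {
    yg <- exp(seq(log(1e-4), log(40), length.out = 600))
    kint <- vapply(yg, function(a) {
      integrate(function(x) besselK(x, 5 / 3), a, Inf,
                rel.tol = 1e-9)$value
    }, numeric(1))
    .rhizo_cache$g1_grid <- list(y = yg, g1 = yg * kint)
  }
  g <- .rhizo_cache$g1_grid
  out <- numeric(length(y))
  inside <- y >= g$y[1] & y <= g$y[length(g$y)]
  out[inside] <- exp(approx(log(g$y), log(g$g1), log(y[inside]))$y)
  # asymptotics outside the cached range
  small <- y < g$y[1]
  out[small] <- 2.1495 * y[small]^(1 / 3)      # G1 -> a * y^{1/3} as y -> 0
  large <- y > g$y[length(g$y)]
  out[large] <- sqrt(pi / 2) * sqrt(y[large]) * exp(-y[large])
  out
}

#' Bending-magnet source spectrum
#'
#' Synthesises the universal vertically-integrated bending-magnet spectrum.
#' The photon density per unit energy is proportional to `G1(E/E_c) / E`
#' with `G1(y) = y * int_y^Inf K_{5/3}(x) dx` (G1 itself is the standard
#' flux per relative bandwidth, so the photon count per absolute energy
#' carries the extra `1/E`), normalised so that the flux summed over
#' `norm_range` equals `total_flux`. See [spectrum_stats()] for the two
#' peak-energy conventions this implies.
#'
#' @param critical_energy critical energy E_c, keV. For a storage ring this
#'   is `0.665 * E[GeV]^2 * B[T]`; 3.0 GeV in a 3.2 T dipole gives 19.15 keV.
#' @param total_flux photons/s/mA integrated over `norm_range`.
#' @param grid_range energy range covered by the bins, keV.
#' @param bin_width bin width, keV.
#' @param norm_range range over which `total_flux` is defined, keV.
#' @return an [xray_spectrum()].
#' @export
bending_magnet_spectrum <- function(critical_energy, total_flux = 4.61e13,
                                    grid_range = c(1, 400), bin_width = 0.5,
                                    norm_range = c(5, 400)) {
  if (critical_energy <= 0) stop("critical_energy must be > 0")
  if (total_flux <= 0) stop("total_flux must be > 0")
  edges <- seq(grid_range[1], grid_range[2], by = bin_width)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  shape <- .g1_universal(ctr / critical_energy) / ctr
  in_norm <- ctr >= norm_range[1] & ctr <= norm_range[2]
  flux <- shape * (total_flux / sum(shape[in_norm]))
  xray_spectrum(edges, flux, provenance = sprintf(
    "bending magnet source, E_c = %.3f keV, %.4g photons/s/mA in %g-%g keV",
    critical_energy, total_flux, norm_range[1], norm_range[2]))
}

#' Filter stacks
#'
#' An ordered list of absorbers, each a [material_mixture()] with a
#' thickness in mm.
#'
#' @param ... filters created with [beam_filter()].
#' @return an object of class `filter_stack`.
#' @export
filter_stack <- function(...) {
  fs <- list(...)
  for (f in fs) stopifnot(inherits(f, "beam_filter"))
  structure(fs, class = "filter_stack")
}

#' @param material a [material_mixture()].
#' @param thickness_mm absorber thickness, mm (>= 0).
#' @rdname filter_stack
#' @export
beam_filter <- function(material, thickness_mm) {
  stopifnot(inherits(material, "material_mixture"), thickness_mm >= 0)
  structure(list(material = material, thickness_mm = thickness_mm),
            class = "beam_filter")
}

#' Attenuate a spectrum through a filter stack
#'
#' Multiplies each bin by `prod_j exp(-(mu/rho)_j rho_j t_j)` evaluated at
#' the bin centers (Beer--Lambert beam hardening).
#'
#' @param spectrum an [xray_spectrum()].
#' @param stack a [filter_stack()] (or a single [beam_filter()]).
#' @return the filtered [xray_spectrum()], with provenance appended.
#' @export
attenuate <- function(spectrum, stack) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (inherits(stack, "beam_filter")) stack <- filter_stack(stack)
  stopifnot(inherits(stack, "filter_stack"))
  ctr <- bin_centers(spectrum)
  flux <- spectrum$flux
  prov <- spectrum$provenance
  for (f in stack) {
    if (f$thickness_mm == 0) next
    mu <- .mu_linear(f$material, ctr)           # 1/cm
    flux <- flux * exp(-mu * f$thickness_mm / 10)
    prov <- c(prov, sprintf("filter: %.4g mm %s", f$thickness_mm,
                            f$material$name))
  }
  xray_spectrum(spectrum$edges, flux, prov)
}

#' Spectrum statistics: peak energy, mean energy, total flux
#'
#' `e_peak` is the center of the maximal-flux bin (ties resolved toward the
#' lower energy) and `e_mean` is the flux-weighted mean of the bin centers.
#' `e_peak_bw` is the peak of the flux-per-relative-bandwidth curve
#' (`flux * E`), the standard synchrotron display convention: beamline
#' spectra are customarily plotted per 0.1 percent bandwidth, so a "peak
#' energy" quoted for a bending-magnet beam is normally read from that
#' curve, not from the photon count per unit energy.
#'
#' @param spectrum an [xray_spectrum()].
#' @return list with `e_peak`, `e_peak_bw`, `e_mean` (keV) and `total`
#'   (photons/s/mA).
#' @export
spectrum_stats <- function(spectrum) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  total <- sum(spectrum$flux)
  if (total <= 0) stop("spectrum statistics undefined for all-zero flux")
  ctr <- bin_centers(spectrum)
  list(e_peak = ctr[which.max(spectrum$flux)],
       e_peak_bw = ctr[which.max(spectrum$flux * ctr)],
       e_mean = sum(ctr * spectrum$flux) / total,
       total = total)
}

#' Quasi-monochromatic spectrum (multilayer-mirror beam model)
#'
#' A Gaussian peak plus an optional uniform low-energy tail. The tail is
#' uniform between 1 keV and `peak - 3 * fwhm` and carries `tail_fraction`
#' of the total flux; the Gaussian carries the rest.
#'
#' @param peak peak energy, keV.
#' @param total_flux photons/s/mA.
#' @param fwhm full width at half maximum of the peak, keV (default 5
#'   percent of the peak energy).
#' @param tail_fraction fraction of the flux in the low-energy tail, in
#'   `[0, 0.5)`.
#' @param grid_range,bin_width energy grid, as for
#'   [bending_magnet_spectrum()].
#' @return an [xray_spectrum()].
#' @export
quasi_mono_spectrum <- function(peak, total_flux, fwhm = 0.05 * peak,
                                tail_fraction = 0.05,
                                grid_range = c(1, 400), bin_width = 0.5) {
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (tail_fraction < 0 || tail_fraction >= 0.5) {
    stop("tail_fraction must be in [0, 0.5)")
  }
  edges <- seq(grid_range[1], grid_range[2], by = bin_width)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  if (peak <= grid_range[1] || peak >= grid_range[2]) {
    stop("peak must lie inside grid_range")
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  g <- dnorm(ctr, peak, sigma)
  g <- g / sum(g)
  tail_hi <- peak - 3 * fwhm
  tl <- as.numeric(ctr >= 1 & ctr <= tail_hi)
  flux <- (1 - tail_fraction) * g * total_flux
  if (tail_fraction > 0) {
    if (sum(tl) == 0) stop("no bins available for the low-energy tail")
    flux <- flux + tail_fraction * total_flux * tl / sum(tl)
  }
  xray_spectrum(edges, flux, provenance = sprintf(
    "quasi-monochromatic source, peak %.3g keV, fwhm %.3g keV, %.3g tail, %.4g photons/s/mA",
    peak, fwhm, tail_fraction, total_flux))
}

#' Read / write spectra as two-column text files
#'
#' The on-disk format is whitespace- or comma-separated text with two
#' columns: bin-center energy (keV) and flux per bin (photons/s/mA). Lines
#' starting with `#` are comments. Energies must be strictly increasing and
#' fluxes non-negative; violations are reported with the offending line
#' number. Bin edges are reconstructed from midpoints between centers, so a
#' write/read round trip on a uniform grid is lossless.
#'
#' @param path file path.
#' @param spectrum an [xray_spectrum()] (for writing).
#' @return `read_spectrum` returns an [xray_spectrum()]; `write_spectrum`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad)) {
    stop("line ", ln[bad[1]], ": expected two columns (energy, flux)")
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value at line ",
                     ln[which(is.na(rowSums(m)))[1]])
  e <- m[, 1]; flux <- m[, 2]
  nd <- which(diff(e) <= 0)
  if (length(nd)) {
    stop("energies not strictly increasing at line ", ln[nd[1] + 1])
  }
  neg <- which(flux < 0)
  if (length(neg)) stop("negative flux at line ", ln[neg[1]])
  if (length(e) < 2) stop("need at least two bins")
  mid <- (e[-1] + e[-length(e)]) / 2
  edges <- c(e[1] - (mid[1] - e[1]), mid, e[length(e)] +
               (e[length(e)] - mid[length(mid)]))
  xray_spectrum(edges, flux, provenance = paste("read from", path))
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rhizodose spectrum: energy_keV flux_photons_per_s_per_mA", con)
  for (p in spectrum$provenance) writeLines(paste("#", p), con)
  writeLines(sprintf("%.17g %.17g", bin_centers(spectrum), spectrum$flux),
             con)
  invisible(path)
}
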