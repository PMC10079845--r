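#' Photon interaction data for a chemical element
#'
#' Returns the packaged interaction data for one element: total mass
#' attenuation and mass energy-absorption coefficients on the tabulated
#' 1--500 keV grid, plus partial coefficients (photoelectric, incoherent,
#' coherent) reconstructed from the total. Absorption edges are represented
#' by duplicated energy nodes; a query exactly at an edge energy uses the
#' above-edge value.
#'
#' The incoherent partial is the free-electron Klein--Nishina cross section,
#' the coherent partial comes from a Thomas--Fermi screened hydrogenic
#' form-factor quadrature, and the photoelectric partial is the residual
#' total minus scattering, clamped at zero. Where the energy-absorption
#' column is not tabulated it is reconstructed as photoelectric (corrected
#' for K-fluorescence escape) plus the Klein--Nishina energy-transfer
#' component.
#'
#' @param symbol chemical symbol, e.g. `"Si"`.
#' @return an object of class `element_data`: list with `symbol`, `Z`, `A`,
#'   `energy` (keV), `mu_rho`, `mu_en_rho`, `photoelectric`, `incoherent`,
#'   `coherent` (all cm^2/g).
#' @export
element_data <- function(symbol) {
  tab <- .element_tables()
  if (!symbol %in% names(tab)) {
    stop("unknown element '", symbol, "'; available: ",
         paste(names(tab), collapse = ", "))
  }
  tab[[symbol]]
}

#' @export
print.element_data <- function(x, ...) {
  cat("<element_data> ", x$symbol, " (Z=", x$Z, ", A=", x$A, " g/mol), ",
      length(x$energy), " energy nodes ",
      min(x$energy), "-", max(x$energy), " keV\n", sep = "")
  invisible(x)
}

# K-edge energies (keV) and K-fluorescence yields for edge handling
.K_EDGE <- c(Ar = 3.2029, K = 3.6074, Ca = 4.0381, Ti = 4.9664, Fe = 7.112)
.K_YIELD <- c(Ar = 0.118, K = 0.140, Ca = 0.163, Ti = 0.219, Fe = 0.340)

.element_tables <- function() {
  if (!is.null(.rhizo_cache$elements)) return(.rhizo_cache$elements)
  path <- system.file("extdata", "xray_mass_coefficients.csv",
                      package = "rhizodose")
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- list()
  for (sym in unique(raw$element)) {
    d <- raw[raw$element == sym, ]
    e <- d$energy_kev
    stopifnot(!is.unsorted(e))
    mu <- d$mu_rho
    men <- d$mu_en_rho
    Z <- d$Z[1]; A <- d$A[1]
    incoh <- .kn_total_sigma(e) * Z * .NA_MOL / A
    coh <- .coherent_sigma(e, Z) * .NA_MOL / A
    # photoelectric as residual; where scattering alone exceeds the total
    # (possible within table precision at high energy) shrink coherent first
    pe <- mu - incoh - coh
    bad <- pe < 0
    if (any(bad)) {
      coh[bad] <- pmax(mu[bad] - incoh[bad], 0)
      pe[bad] <- pmax(mu[bad] - incoh[bad] - coh[bad], 0)
    }
    if (anyNA(men)) {
      fkn <- .kn_transfer_fraction(e)
      fl <- rep(1, length(e))
      if (sym %in% names(.K_EDGE)) {
        above <- e >= .K_EDGE[[sym]]
        # ~7/8 of the photoelectric cross section is K-shell above the edge
        fl[above] <- 1 - 0.875 * .K_YIELD[[sym]] * .K_EDGE[[sym]] / e[above]
      }
      men <- pe * fl + incoh * fkn
    }
    men <- pmin(men, mu)
    out[[sym]] <- structure(
      list(symbol = sym, Z = Z, A = A, energy = e, mu_rho = mu,
           mu_en_rho = men, photoelectric = pe, incoherent = incoh,
           coherent = coh),
      class = "element_data")
  }
  .rhizo_cache$elements <- out
  out
}

# total Klein-Nishina cross section per electron, cm^2 (vectorised in keV)
.kn_total_sigma <- function(energy_kev) {
  a <- energy_kev / .ME_KEV
  t <- 1 + 2 * a
  sig <- (1 + a) / a^2 * (2 * (1 + a) / t - log(t) / a) +
    log(t) / (2 * a) - (1 + 3 * a) / t^2
  2 * pi * .RE_CM^2 * sig
}

# mean fraction of photon energy transferred to the electron per incoherent
# interaction (Klein-Nishina), by quadrature over the scattering angle
.kn_transfer_fraction <- function(energy_kev) {
  vapply(energy_kev, function(E) {
    a <- E / .ME_KEV
    mu <- seq(-1, 1, length.out = 2001)
    x <- 1 + a * (1 - mu)            # E/E'
    # KN differential cross section (unnormalised) in cos(theta)
    dkn <- (1 / x^2) * (x + 1 / x - (1 - mu^2))
    w <- .simpson_weights(length(mu))
    sum(w * dkn * (1 - 1 / x)) / sum(w * dkn)
  }, numeric(1))
}

.simpson_weights <- function(n) {
  stopifnot(n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w
}

# coherent (Rayleigh) cross section per atom, cm^2, using a screened
# hydrogenic atomic form factor with Thomas-Fermi screening length
.coherent_sigma <- function(energy_kev, Z) {
  a0 <- 5.29177210903e-9                    # Bohr radius, cm
  hbarc <- 1.973269804e-8                   # keV * cm
  as <- 0.885 * a0 * Z^(-1 / 3)             # screening length, cm
  mu <- seq(-1, 1, length.out = 1001)
  w <- .simpson_weights(length(mu))
  dmu <- 2 / (length(mu) - 1)
  vapply(energy_kev, function(E) {
    s2 <- (1 - mu) / 2                      # sin^2(theta/2)
    q_as <- 2 * E * sqrt(s2) * as / hbarc   # q * a_s / hbar (dimensionless)
    ff <- 1 / (1 + (q_as / 2)^2)^2          # F(q)/Z
    integrand <- (1 + mu^2) * (Z * ff)^2
    pi * .RE_CM^2 * sum(w * integrand) * dmu / 3
  }, numeric(1))
}

# log-log interpolation honouring duplicated edge nodes; query exactly at an
# edge returns the above-edge value; energies outside the table are an error
.loglog_interp <- function(e_tab, v_tab, energy) {
  if (any(energy < e_tab[1] | energy > e_tab[length(e_tab)])) {
    stop("energy outside tabulated range [", e_tab[1], ", ",
         e_tab[length(e_tab)], "] keV")
  }
  # findInterval with duplicated nodes returns the LAST index with e <= x,
  # i.e. the above-edge row when querying exactly at an edge
  i <- findInterval(energy, e_tab)
  i[i == length(e_tab)] <- length(e_tab) - 1L
  exact <- e_tab[i] == energy
  lo <- i; hi <- i + 1L
  f <- ifelse(exact, 0,
              (log(energy) - log(e_tab[lo])) /
                (log(e_tab[hi]) - log(e_tab[lo])))
  out <- exp((1 - f) * log(v_tab[lo]) + f * log(v_tab[hi]))
  out[exact] <- v_tab[i][exact]
  out
}

#' Define a material as a mixture of elements
#'
#' @param composition named numeric vector of elemental mass fractions
#'   (names are chemical symbols present in the packaged tables); must sum
#'   to 1 within 1e-9.
#' @param density bulk density, g/cm^3.
#' @param name label used in printing and provenance strings.
#' @return an object of class `material_mixture`.
#' @export
material_mixture <- function(composition, density, name = "material") {
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", format(sum(composition)), ")")
  }
  if (any(composition < 0)) stop("mass fractions must be >= 0")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  tabs <- .element_tables()
  unknown <- setdiff(names(composition), names(tabs))
  if (length(unknown)) stop("no tables for element(s): ",
                            paste(unknown, collapse = ", "))
  structure(list(composition = composition, density = density, name = name),
            class = "material_mixture")
}

#' @export
print.material_mixture <- function(x, ...) {
  cat("<material_mixture> ", x$name, " (", format(x$density), " g/cm^3)\n",
      sep = "")
  comp <- sort(x$composition, decreasing = TRUE)
  cat(" ", paste(sprintf("%s %.4f", names(comp), comp), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Mass interaction coefficient of a mixture
#'
#' Applies the standard mixture rule `sum_i w_i c_i(E)` with log--log
#' interpolation between tabulated nodes (exact at the nodes).
#'
#' @param mixture a [material_mixture()].
#' @param energy photon energy or energies, keV (within 1--500 keV).
#' @param kind one of `"total"`, `"energy_absorption"`, `"photoelectric"`,
#'   `"incoherent"`, `"coherent"`.
#' @return coefficient(s) in cm^2/g.
#' @export
mass_coefficient <- function(mixture, energy,
                             kind = c("total", "energy_absorption",
                                      "photoelectric", "incoherent",
                                      "coherent")) {
  kind <- match.arg(kind)
  stopifnot(inherits(mixture, "material_mixture"))
  field <- switch(kind, total = "mu_rho", energy_absorption = "mu_en_rho",
                  photoelectric = "photoelectric", incoherent = "incoherent",
                  coherent = "coherent")
  out <- numeric(length(energy))
  for (sym in names(mixture$composition)) {
    el <- element_data(sym)
    out <- out + mixture$composition[[sym]] *
      .loglog_interp(el$energy, el[[field]], energy)
  }
  out
}

# linear attenuation coefficient, 1/cm
.mu_linear <- function(mixture, energy, kind = "total") {
  mass_coefficient(mixture, energy, kind) * mixture$density
}

#' Stock materials
#'
#' Convenience constructors for the materials used by the packaged
#' scenarios: water (also the root tissue model), standard dry air at
#' 0.001225 g/cm^3, crystalline silicon (filters) and diamond (the beamline
#' exit window).
#'
#' @return a [material_mixture()].
#' @export
mat_water <- function() {
  material_mixture(c(H = 0.1119, O = 0.8881), 1.0, "water")
}

#' @rdname mat_water
#' @export
mat_air <- function() {
  w <- c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012827)
  material_mixture(w / sum(w), 0.001225, "air")
}

#' @rdname mat_water
#' @export
mat_silicon <- function() material_mixture(c(Si = 1), 2.329, "silicon")

#' @rdname mat_water
#' @export
mat_diamond <- function() material_mixture(c(C = 1), 3.515, "diamond")

#' @rdname mat_water
#' @export
mat_root <- function() {
  m <- mat_water()
  m$name <- "root (water)"
  m
}

#' Specify a soil: solid composition plus pore structure
#'
#' @param solid_fractions named numeric vector, elemental mass fractions of
#'   the solid phase (sum to 1).
#' @param solid_density particle density of the solid phase, g/cm^3.
#' @param porosity pore volume fraction (v/v).
#' @param water_fraction,air_fraction volume fractions of pore water and pore
#'   air; must sum to `porosity`.
#' @param water_density,air_density densities of the pore fluids, g/cm^3.
#' @return an object of class `soil_spec`.
#' @export
soil_spec <- function(solid_fractions, solid_density = 2.7, porosity = 0.30,
                      water_fraction = 0.15, air_fraction = 0.15,
                      water_density = 1.0, air_density = 0.001225) {
  if (abs(sum(solid_fractions) - 1) > 1e-9) {
    stop("solid mass fractions must sum to 1")
  }
  fr <- c(porosity, water_fraction, air_fraction)
  if (any(fr < 0 | fr > 1)) stop("volume fractions must be in [0, 1]")
  if (abs(porosity - (water_fraction + air_fraction)) > 1e-9) {
    stop("porosity must equal water_fraction + air_fraction")
  }
  structure(list(solid_fractions = solid_fractions,
                 solid_density = solid_density, porosity = porosity,
                 water_fraction = water_fraction,
                 air_fraction = air_fraction,
                 water_density = water_density, air_density = air_density),
            class = "soil_spec")
}

#' @export
print.soil_spec <- function(x, ...) {
  cat("<soil_spec> solid ", format(x$solid_density), " g/cm^3, porosity ",
      format(100 * x$porosity), "% (water ", format(100 * x$water_fraction),
      "%, air ", format(100 * x$air_fraction), "%)\n", sep = "")
  comp <- sort(x$solid_fractions, decreasing = TRUE)
  cat(" solid: ", paste(sprintf("%s %.3f", names(comp), comp),
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Bulk soil material from a soil specification
#'
#' The bulk density is the volume-weighted mean of the solid, water and air
#' phases: `(1 - porosity) * rho_solid + f_w * rho_w + f_a * rho_a`.
#' Elemental mass fractions are recomputed from the mass contributions of
#' the three phases (the air mass is negligible but included).
#'
#' @param spec a [soil_spec()].
#' @return a [material_mixture()] for the bulk soil.
#' @export
bulk_soil_material <- function(spec) {
  stopifnot(inherits(spec, "soil_spec"))
  m_solid <- (1 - spec$porosity) * spec$solid_density
  m_water <- spec$water_fraction * spec$water_density
  m_air <- spec$air_fraction * spec$air_density
  rho <- m_solid + m_water + m_air
  add <- function(acc, comp, mass) {
    for (s in names(comp)) {
      acc[s] <- (if (s %in% names(acc)) acc[[s]] else 0) + comp[[s]] * mass
    }
    acc
  }
  masses <- numeric(0)
  if (m_solid > 0) masses <- add(masses, spec$solid_fractions, m_solid)
  if (m_water > 0) masses <- add(masses, mat_water()$composition, m_water)
  if (m_air > 0) masses <- add(masses, mat_air()$composition, m_air)
  material_mixture(masses / sum(masses), rho, "bulk soil")
}

#' Packaged default soil composition
#'
#' A nine-element Oxisol-like tropical soil emulation: a kaolinitic /
#' gibbsitic mineral assemblage with quartz, a few percent iron oxide,
#' minor Ti/K/Ca and some organic carbon, such that oxygen, silicon and
#' aluminium together make up about 90 percent of the solid mass. Solid
#' particle density 2.7 g/cm^3, porosity 30 percent (v/v) split equally
#' between water and air. This is a documented emulation of a measured
#' nine-element composition, not a measured soil.
#'
#' @return a [soil_spec()].
#' @export
load_default_soil <- function() {
  comp <- c(O = 0.545, Si = 0.210, Al = 0.155, Fe = 0.025, C = 0.030,
            Ti = 0.008, K = 0.008, Ca = 0.008, H = 0.011)
  soil_spec(comp)
}

#' Read / write a soil specification as plain-text CSV
#'
#' The format is a two-column CSV (`key,value`). Rows whose key is one of
#' `solid_density`, `porosity`, `water_fraction`, `air_fraction`,
#' `water_density`, `air_density` set those parameters; every other row is
#' taken as an element symbol with its solid mass fraction. Lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @param spec a [soil_spec()] (for writing).
#' @return `read_soil_spec` returns a [soil_spec()]; `write_soil_spec`
#'   returns `path` invisibly.
#' @export
read_soil_spec <- function(path) {
  d <- read.csv(path, header = FALSE, comment.char = "#",
                stringsAsFactors = FALSE,
                col.names = c("key", "value"))
  pars <- c("solid_density", "porosity", "water_fraction", "air_fraction",
            "water_density", "air_density")
  is_par <- d$key %in% pars
  args <- as.list(setNames(as.numeric(d$value[is_par]), d$key[is_par]))
  comp <- setNames(as.numeric(d$value[!is_par]), d$key[!is_par])
  if (length(comp) != 9) {
    message("soil composition has ", length(comp),
            " elements (packaged default has 9)")
  }
  do.call(soil_spec, c(list(solid_fractions = comp), args))
}

#' @rdname read_soil_spec
#' @export
write_soil_spec <- function(spec, path) {
  stopifnot(inherits(spec, "soil_spec"))
  pars <- data.frame(
    key = c("solid_density", "porosity", "water_fraction", "air_fraction",
            "water_density", "air_density"),
    value = c(spec$solid_density, spec$porosity, spec$water_fraction,
              spec$air_fraction, spec$water_density, spec$air_density))
  comp <- data.frame(key = names(spec$solid_fractions),
                     value = unname(spec$solid_fractions))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rhizodose soil specification", con)
  write.table(rbind(pars, comp), con, sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}
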