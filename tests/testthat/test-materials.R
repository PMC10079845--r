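test_that("mixture rule is exact at nodes and linear in composition", {
  si <- material_mixture(c(Si = 1), 2.329)
  expect_equal(mass_coefficient(si, 30), 1.436)     # tabulated node
  expect_equal(mass_coefficient(si, 50), 0.4385)
  o <- material_mixture(c(O = 1), 1)
  mix <- material_mixture(c(Si = 0.5, O = 0.5), 1)
  for (e in c(17.3, 42, 77)) {
    expect_equal(mass_coefficient(mix, e),
                 (mass_coefficient(si, e) + mass_coefficient(o, e)) / 2)
  }
})

test_that("water total attenuation matches the reference value at 50 keV", {
  expect_equal(mass_coefficient(mat_water(), 50), 0.2269, tolerance = 1e-3)
})

test_that("interpolation is monotone between adjacent nodes", {
  el <- element_data("O")
  e <- seq(30, 40, length.out = 21)
  v <- mass_coefficient(material_mixture(c(O = 1), 1), e)
  expect_true(all(diff(v) < 0))
})

test_that("coefficients queried at an absorption edge use the above-edge value", {
  fe <- material_mixture(c(Fe = 1), 7.874)
  expect_equal(mass_coefficient(fe, 7.112), 407.6)
})

test_that("element tables satisfy their physical invariants", {
  for (sym in c("H", "C", "O", "Al", "Si", "K", "Ca", "Ti", "Fe")) {
    el <- element_data(sym)
    expect_true(all(diff(el$energy) >= 0), info = sym)
    expect_true(all(el$mu_rho > 0), info = sym)
    expect_true(all(el$mu_en_rho <= el$mu_rho * (1 + 1e-12)), info = sym)
    ps <- el$photoelectric + el$incoherent + el$coherent
    # away from edges (> 1 keV above any edge) the partials must add up
    away <- el$energy > 9
    expect_lt(max(abs(ps[away] - el$mu_rho[away]) / el$mu_rho[away]), 0.02)
  }
})

test_that("mixture coefficient equals the mass-fraction-weighted sum", {
  a <- material_mixture(c(Si = 0.6, O = 0.4), 2)
  for (e in c(12, 33, 150)) {
    expect_equal(mass_coefficient(a, e),
                 0.6 * mass_coefficient(material_mixture(c(Si = 1), 2), e) +
                   0.4 * mass_coefficient(material_mixture(c(O = 1), 2), e))
  }
})

test_that("invalid mixtures and out-of-range energies are rejected", {
  expect_error(material_mixture(c(Si = 0.7, O = 0.2), 2), "sum to 1")
  expect_error(material_mixture(c(Si = 1), -2), "density")
  expect_error(mass_coefficient(mat_water(), 700), "outside")
  expect_error(mass_coefficient(mat_water(), 0.5), "outside")
})

test_that("bulk soil density is the closed-form weighted mean", {
  spec <- load_default_soil()
  bulk <- bulk_soil_material(spec)
  expect_equal(bulk$density,
               0.70 * 2.7 + 0.15 * 1.0 + 0.15 * 0.001225,
               tolerance = 1e-12)
  expect_equal(bulk$density, 2.04, tolerance = 1e-3)
  expect_equal(sum(bulk$composition), 1, tolerance = 1e-12)
})

test_that("degenerate soils reduce to their single phase", {
  solid <- c(O = 0.533, Si = 0.467)
  s0 <- soil_spec(solid, porosity = 0, water_fraction = 0, air_fraction = 0)
  expect_equal(bulk_soil_material(s0)$density, 2.7)
  s1 <- soil_spec(solid, porosity = 1, water_fraction = 1, air_fraction = 0)
  b1 <- bulk_soil_material(s1)
  expect_equal(b1$density, 1.0)
  expect_equal(b1$composition[["O"]], 0.8881, tolerance = 1e-12)
  expect_equal(b1$composition[["H"]], 0.1119, tolerance = 1e-12)
})

test_that("default soil has nine elements dominated by O, Si and Al", {
  spec <- load_default_soil()
  expect_length(spec$solid_fractions, 9)
  expect_equal(sum(spec$solid_fractions), 1, tolerance = 1e-12)
  expect_gte(sum(spec$solid_fractions[c("O", "Si", "Al")]), 0.88)
  expect_equal(spec$porosity,
               spec$water_fraction + spec$air_fraction)
})

test_that("soil specs round-trip through CSV, including non-default ones", {
  path <- tempfile(fileext = ".csv")
  spec <- load_default_soil()
  write_soil_spec(spec, path)
  back <- read_soil_spec(path)
  expect_equal(back$solid_fractions, spec$solid_fractions)
  expect_equal(back$porosity, spec$porosity)
  # an 8-element override is accepted but reported
  spec8 <- soil_spec(spec$solid_fractions[1:8] /
                       sum(spec$solid_fractions[1:8]))
  write_soil_spec(spec8, path)
  expect_message(read_soil_spec(path), "8 elements")
})
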