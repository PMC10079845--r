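test_that("the universal bending-magnet function matches direct quadrature", {
  g1_direct <- function(y) {
    y * integrate(function(x) besselK(x, 5 / 3), y, Inf, rel.tol = 1e-10)$value
  }
  ys <- c(0.05, 0.3, 0.83, 2, 7, 15)
  expect_equal(rhizodose:::.g1_universal(ys),
               vapply(ys, g1_direct, numeric(1)), tolerance = 1e-3)
  # large-argument decay ~ sqrt(pi/2) sqrt(y) exp(-y)
  y <- 25
  expect_equal(g1_direct(y) / (sqrt(pi / 2) * sqrt(y) * exp(-y)), 1,
               tolerance = 0.03)
})

test_that("bending-magnet spectrum is normalised and linear in total flux", {
  bc <- bending_magnet_spectrum(19.15, total_flux = 4.61e13)
  ctr <- bin_centers(bc)
  in_norm <- ctr >= 5 & ctr <= 400
  expect_equal(sum(bc$flux[in_norm]), 4.61e13, tolerance = 1e-9)
  bc2 <- bending_magnet_spectrum(19.15, total_flux = 2 * 4.61e13)
  expect_equal(bc2$flux, 2 * bc$flux)
  s1 <- spectrum_stats(bc); s2 <- spectrum_stats(bc2)
  expect_equal(s1$e_peak, s2$e_peak)
  expect_equal(s1$e_mean, s2$e_mean)
  expect_error(bending_magnet_spectrum(-1), "critical_energy")
})

test_that("attenuation composes, never gains flux, and hardens the beam", {
  bc <- bending_magnet_spectrum(19.15)
  expect_equal(attenuate(bc, beam_filter(mat_silicon(), 0))$flux, bc$flux)
  one <- attenuate(bc, beam_filter(mat_silicon(), 1.0))
  two <- attenuate(attenuate(bc, beam_filter(mat_silicon(), 0.4)),
                   beam_filter(mat_silicon(), 0.6))
  expect_equal(one$flux, two$flux, tolerance = 1e-12)
  expect_true(all(one$flux <= bc$flux))
  expect_gt(spectrum_stats(one)$e_mean, spectrum_stats(bc)$e_mean)
})

test_that("spectrum statistics handle degenerate shapes", {
  edges <- seq(1, 400, by = 0.5)
  f <- numeric(length(edges) - 1)
  f[100] <- 5
  sp <- xray_spectrum(edges, f)
  st <- spectrum_stats(sp)
  ctr <- bin_centers(sp)
  expect_equal(st$e_peak, ctr[100])
  expect_equal(st$e_mean, ctr[100])
  # symmetric triangle about bin 200
  f2 <- numeric(length(ctr))
  f2[190:210] <- 11 - abs(-10:10)
  st2 <- spectrum_stats(xray_spectrum(edges, f2))
  expect_equal(st2$e_mean, ctr[200])
  expect_error(spectrum_stats(xray_spectrum(edges, numeric(length(ctr)))),
               "all-zero")
})

test_that("quasi-monochromatic construction meets its flux bookkeeping", {
  sp <- quasi_mono_spectrum(67.5, total_flux = 1.47e8)
  expect_equal(spectrum_stats(sp)$total, 1.47e8, tolerance = 1e-12)
  # narrow peak without tail converges on the peak energy
  sp0 <- quasi_mono_spectrum(40, 1e9, fwhm = 0.6, tail_fraction = 0)
  expect_equal(spectrum_stats(sp0)$e_mean, 40, tolerance = 1e-3)
  # tail fraction lands exactly below the peak - 3*fwhm cut
  sp2 <- quasi_mono_spectrum(40, 1e9, tail_fraction = 0.2)
  ctr <- bin_centers(sp2)
  cut <- 40 - 3 * 0.05 * 40
  expect_equal(sum(sp2$flux[ctr < cut]) / sum(sp2$flux), 0.2,
               tolerance = 1e-6)
  expect_error(quasi_mono_spectrum(40, 1e9, tail_fraction = 0.7),
               "tail_fraction")
})

test_that("spectrum text files round-trip and reject malformed input", {
  sp <- quasi_mono_spectrum(22, 6.01e9)
  path <- tempfile(fileext = ".txt")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(bin_centers(back), bin_centers(sp), tolerance = 1e-12)
  expect_equal(back$flux, sp$flux, tolerance = 1e-12)
  # comment lines are ignored
  writeLines(c("# a comment", "1 4", "# another", "2 5", "3 6"), path)
  expect_equal(read_spectrum(path)$flux, c(4, 5, 6))
  # descending energies rejected with the offending line number
  writeLines(c("1 4", "3 5", "2 6"), path)
  expect_error(read_spectrum(path), "line 3")
  writeLines(c("1 4", "2 -5"), path)
  expect_error(read_spectrum(path), "negative flux")
})
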