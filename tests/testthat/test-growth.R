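make_cyl_mask <- function(dims, radius_vox, n_slices) {
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
  disc <- outer(seq_len(dims[1]) - cx, seq_len(dims[2]) - cy,
                function(i, j) i^2 + j^2) <= radius_vox^2
  m <- array(FALSE, dims)
  m[, , seq_len(n_slices)] <- disc
  m
}

test_that("tip advance measures constructed growth exactly", {
  a <- make_cyl_mask(c(15, 15, 300), 4, 100)
  b <- make_cyl_mask(c(15, 15, 300), 4, 200)
  expect_equal(growth_between(a, b, 0.00288), 100 * 0.00288)
  expect_equal(growth_between(a, a, 0.00288), 0)
  expect_equal(growth_between(a, b, 0.00288, method = "voxel_count"),
               100 * 0.00288)
  expect_error(growth_between(array(FALSE, c(2, 2, 2)), a, 1), "non-empty")
})

test_that("tip advance is additive over nested masks", {
  dims <- c(10, 10, 400)
  m1 <- make_cyl_mask(dims, 3, 50)
  m2 <- make_cyl_mask(dims, 3, 170)
  m3 <- make_cyl_mask(dims, 3, 260)
  v <- 0.01
  expect_equal(growth_between(m1, m2, v) + growth_between(m2, m3, v),
               growth_between(m1, m3, v))
})

test_that("a tilted root's tip advance stays close to the true advance", {
  dims <- c(60, 60, 200)
  tilt <- function(n_slices) {
    m <- array(FALSE, dims)
    for (k in seq_len(n_slices)) {
      ci <- 10 + round(0.2 * k); cj <- 30
      ii <- pmax(1, ci - 3):pmin(dims[1], ci + 3)
      m[ii, (cj - 3):(cj + 3), k] <- TRUE
    }
    m
  }
  a <- tilt(80); b <- tilt(160)
  # axial advance 80 voxels; the tilt (slope 0.2) makes the true axis
  # advance 80*sqrt(1+0.04) -- tip_advance reports the axial component
  expect_equal(growth_between(a, b, 0.01), 0.8, tolerance = 0.05)
})

test_that("growth rates divide advances by the interval durations", {
  dims <- c(12, 12, 500)
  masks <- lapply(c(100, 308, 400), make_cyl_mask, dims = dims,
                  radius_vox = 3)
  ser <- root_mask_series(masks, 0.00288, times_h = c(0, 1, 2.5))
  r <- growth_rates(ser)
  expect_equal(r$rate_mm_h[1], 208 * 0.00288 / 1)
  expect_equal(r$rate_mm_h[2], 92 * 0.00288 / 1.5)
  # constant series gives zero rates
  ser0 <- root_mask_series(list(masks[[1]], masks[[1]]), 0.00288, c(0, 1))
  expect_equal(growth_rates(ser0)$rate_mm_h, 0)
  expect_error(root_mask_series(masks, 0.00288, c(0, 1, 1)),
               "strictly increasing")
})

test_that("dose response recovers exact linear data and honours exclusions", {
  doses <- c(0, 5700, 11400, 17100)
  rates <- 0.7 - 2e-5 * doses
  fit <- dose_response(rates, doses)
  expect_equal(fit$slope, -2e-5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.7, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(coef(fit)), c(0.7, -2e-5), tolerance = 1e-10)
  expect_equal(unname(predict(fit, 1000)), 0.7 - 0.02, tolerance = 1e-10)
  # excluding a plateau point reproduces the fit without it
  rates2 <- c(rates, 0)
  doses2 <- c(doses, 22800)
  f2 <- dose_response(rates2, doses2, exclude = 5)
  expect_equal(f2$slope, fit$slope)
  expect_equal(f2$intercept, fit$intercept)
  expect_error(dose_response(c(1, 2), c(3, 3)), "degenerate")
  expect_error(dose_response(1, c(1, 2)), "lengths differ")
})

test_that("root masks round-trip through the CSV voxel-list format", {
  m <- make_cyl_mask(c(8, 8, 30), 2, 12)
  path <- tempfile(fileext = ".csv")
  write_root_mask(m, path, voxel_mm = 0.01)
  back <- read_root_mask(path)
  expect_identical(back$mask, m)
  expect_equal(back$voxel_mm, 0.01)
})
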