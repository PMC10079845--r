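#' Time series of segmented root masks
#'
#' @param masks list of 3D logical arrays (same dimensions); `TRUE` marks
#'   root voxels. The third array dimension is the growth axis.
#' @param voxel_mm isotropic voxel size, mm.
#' @param times_h acquisition times, hours, strictly increasing.
#' @return an object of class `root_mask_series`.
#' @export
root_mask_series <- function(masks, voxel_mm = 0.00288, times_h) {
  stopifnot(is.list(masks), length(masks) >= 1)
  d <- dim(masks[[1]])
  for (m in masks) {
    if (!is.logical(m) || length(dim(m)) != 3 || !all(dim(m) == d)) {
      stop("masks must be 3D logical arrays with identical dimensions")
    }
  }
  if (length(times_h) != length(masks) || any(diff(times_h) <= 0)) {
    stop("times_h must be strictly increasing, one per mask")
  }
  if (voxel_mm <= 0) stop("voxel size must be > 0")
  structure(list(masks = masks, voxel_mm = voxel_mm, times_h = times_h),
            class = "root_mask_series")
}

#' @export
print.root_mask_series <- function(x, ...) {
  cat("<root_mask_series> ", length(x$masks), " timepoints, grid ",
      paste(dim(x$masks[[1]]), collapse = "x"), ", voxel ",
      x$voxel_mm * 1000, " um\n", sep = "")
  invisible(x)
}

#' Root growth between two segmented masks
#'
#' `tip_advance` (default) measures the advance of the maximal root extent
#' along the growth axis. `voxel_count` counts newly occupied voxels,
#' converts to volume and divides by the mean root cross-sectional area, so
#' it also reports a length.
#'
#' @param mask_a,mask_b 3D logical arrays on the same grid, `mask_b`
#'   acquired after `mask_a`.
#' @param voxel_mm voxel size, mm.
#' @param method `"tip_advance"` or `"voxel_count"`.
#' @return growth in mm.
#' @export
growth_between <- function(mask_a, mask_b, voxel_mm,
                           method = c("tip_advance", "voxel_count")) {
  method <- match.arg(method)
  if (!any(mask_a) || !any(mask_b)) stop("masks must be non-empty")
  if (!all(dim(mask_a) == dim(mask_b))) stop("masks must share a grid")
  occ_slices <- function(m) which(apply(m, 3, any))
  if (method == "tip_advance") {
    (max(occ_slices(mask_b)) - max(occ_slices(mask_a))) * voxel_mm
  } else {
    new_vox <- sum(mask_b & !mask_a)
    sl <- occ_slices(mask_b)
    area <- mean(apply(mask_b[, , sl, drop = FALSE], 3, sum)) * voxel_mm^2
    new_vox * voxel_mm^3 / area
  }
}

#' Per-interval root growth rates
#'
#' @param series a [root_mask_series()].
#' @param method passed to [growth_between()].
#' @return data.frame with `interval`, `dt_h` and `rate_mm_h`.
#' @export
growth_rates <- function(series, method = "tip_advance") {
  stopifnot(inherits(series, "root_mask_series"))
  n <- length(series$masks)
  if (n < 2) stop("need at least two timepoints")
  dt <- diff(series$times_h)
  if (any(dt <= 0)) stop("time intervals must be positive")
  g <- vapply(seq_len(n - 1), function(i) {
    growth_between(series$masks[[i]], series$masks[[i + 1]],
                   series$voxel_mm, method)
  }, numeric(1))
  data.frame(interval = seq_len(n - 1), dt_h = dt, rate_mm_h = g / dt)
}

#' Linear dose-response fit of growth rate on cumulative dose
#'
#' Ordinary least squares of growth rate (mm/h) on cumulative absorbed dose
#' (Gy), with optional point exclusions (e.g. plateau points where growth
#' had already arrested).
#'
#' @param rates growth rates, mm/h.
#' @param doses cumulative doses, Gy, same length.
#' @param exclude integer indices of points excluded from the fit (they are
#'   kept in the object and echoed by the methods).
#' @return an object of class `dose_response` with `print`, `summary`,
#'   `coef`, `predict`, `residuals` and `plot` methods. The slope is in
#'   mm/h per Gy.
#' @export
dose_response <- function(rates, doses, exclude = NULL) {
  if (length(rates) != length(doses)) stop("rates and doses lengths differ")
  keep <- setdiff(seq_along(rates), exclude)
  if (length(keep) < 2) stop("need at least 2 included points")
  if (diff(range(doses[keep])) == 0) {
    stop("doses are degenerate (all equal); slope undefined")
  }
  d <- data.frame(dose = doses, rate = rates)
  fit <- lm(rate ~ dose, data = d[keep, , drop = FALSE])
  # summary.lm warns on exact (zero-residual) data; that case is legitimate
  # here (noise-free generator output), so keep it quiet
  sm <- suppressWarnings(summary(fit))
  structure(list(fit = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 data = d, included = keep, excluded = exclude),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("<dose_response> growth rate vs cumulative dose\n")
  cat(sprintf("  slope: %.4g mm/h per Gy (SE %.3g)\n", x$slope, x$slope_se))
  cat(sprintf("  intercept: %.4g mm/h, R^2 = %.3f\n", x$intercept,
              x$r_squared))
  if (length(x$excluded)) {
    cat("  excluded points:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.dose_response <- function(object, ...) {
  s <- summary(object$fit, ...)
  s$excluded <- object$excluded
  s
}

#' @export
coef.dose_response <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.dose_response <- function(object, doses = NULL, ...) {
  if (is.null(doses)) doses <- object$data$dose
  predict(object$fit, newdata = data.frame(dose = doses), ...)
}

#' @export
residuals.dose_response <- function(object, ...) {
  object$data$rate[object$included] -
    predict(object, object$data$dose[object$included])
}

#' @export
plot.dose_response <- function(x, ...) {
  inc <- x$included
  graphics::plot(x$data$dose / 1000, x$data$rate,
                 xlab = "cumulative dose (kGy)",
                 ylab = "growth rate (mm/h)",
                 pch = ifelse(seq_len(nrow(x$data)) %in% inc, 19, 1), ...)
  graphics::abline(x$intercept, x$slope * 1000)
  invisible(x)
}

#' Plain-text IO for root masks
#'
#' Masks are stored as a CSV of occupied voxel indices with a header
#' carrying the grid dimensions and voxel size.
#'
#' @param mask 3D logical array.
#' @param path file path.
#' @param voxel_mm voxel size recorded in the header.
#' @return `read_root_mask` returns a list with `mask` and `voxel_mm`;
#'   `write_root_mask` returns `path` invisibly.
#' @export
write_root_mask <- function(mask, path, voxel_mm = 0.00288) {
  idx <- which(mask, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims=%s voxel_mm=%.8g",
                     paste(dim(mask), collapse = "x"), voxel_mm), con)
  writeLines("i,j,k", con)
  writeLines(sprintf("%d,%d,%d", idx[, 1], idx[, 2], idx[, 3]), con)
  invisible(path)
}

#' @rdname write_root_mask
#' @export
read_root_mask <- function(path) {
  hdr <- readLines(path, n = 1)
  dims <- as.integer(strsplit(sub(".*dims=([0-9x]+).*", "\\1", hdr),
                              "x")[[1]])
  voxel <- as.numeric(sub(".*voxel_mm=([0-9.eE+-]+).*", "\\1", hdr))
  d <- read.csv(path, skip = 1)
  mask <- array(FALSE, dims)
  mask[as.matrix(d)] <- TRUE
  list(mask = mask, voxel_mm = voxel)
}
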