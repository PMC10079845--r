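#' Sample geometry: soil cylinder with an off-center root cylinder
#'
#' The sample is a vertical soil cylinder (axis along z) containing a
#' vertical water-filled root cylinder whose axis is offset by `root_offset`
#' from the rotation axis. The beam travels along +x. The rotation angle
#' `theta` (degrees) places the root azimuthally: `theta = 0` puts the root
#' on the upstream side, directly in front of the beam; rotation is
#' clockwise viewed from above, so the root center sits at
#' `(x, y) = root_offset * (-cos(theta), sin(theta))`.
#'
#' @param soil_radius soil cylinder radius, mm.
#' @param soil_height soil cylinder height, mm.
#' @param root_radius root cylinder radius, mm.
#' @param root_offset radial distance of the root axis from the rotation
#'   axis, mm; the root must lie fully inside the soil.
#' @param root_height root cylinder height, mm.
#' @param theta rotation angle, degrees (wrapped modulo 360).
#' @param soil_material,root_material [material_mixture()] objects; defaults
#'   are the packaged bulk soil and water.
#' @return an object of class `sample_geometry`.
#' @export
sample_geometry <- function(soil_radius = 1.45, soil_height = 5.25,
                            root_radius = 0.3, root_offset = 1.0,
                            root_height = 5.25, theta = 0,
                            soil_material = NULL, root_material = NULL) {
  if (root_offset + root_radius > soil_radius + 1e-12) {
    stop("root must lie fully inside the soil cylinder")
  }
  if (is.null(soil_material)) {
    soil_material <- bulk_soil_material(load_default_soil())
  }
  if (is.null(root_material)) root_material <- mat_root()
  structure(list(soil_radius = soil_radius, soil_height = soil_height,
                 root_radius = root_radius, root_offset = root_offset,
                 root_height = root_height, theta = theta %% 360,
                 soil_material = soil_material,
                 root_material = root_material),
            class = "sample_geometry")
}

#' @export
print.sample_geometry <- function(x, ...) {
  cat("<sample_geometry> soil r=", x$soil_radius, " mm (h=", x$soil_height,
      "), root r=", x$root_radius, " mm at offset ", x$root_offset,
      " mm, theta=", x$theta, " deg\n", sep = "")
  invisible(x)
}

# root axis position (x, y) in beam coordinates for the current theta
.root_center <- function(geometry) {
  th <- geometry$theta * pi / 180
  geometry$root_offset * c(-cos(th), sin(th))
}

#' Rotate the sample
#'
#' Advances the root azimuth clockwise by `dtheta` degrees; the soil
#' cylinder is axially symmetric and unchanged.
#'
#' @param geometry a [sample_geometry()].
#' @param dtheta rotation increment, degrees.
#' @return the rotated [sample_geometry()].
#' @export
rotate_sample <- function(geometry, dtheta) {
  stopifnot(inherits(geometry, "sample_geometry"))
  geometry$theta <- (geometry$theta + dtheta) %% 360
  geometry
}

# parametric interval [t0, t1] where an infinite ray origin + t*dir lies
# inside a vertical cylinder (center cx, cy, radius r, z in [zlo, zhi]);
# returns NULL when the ray misses
.ray_cylinder <- function(origin, dir, cx, cy, r, zlo, zhi) {
  a <- dir[1]^2 + dir[2]^2
  ox <- origin[1] - cx; oy <- origin[2] - cy
  if (a < 1e-300) {
    if (ox^2 + oy^2 >= r^2) return(NULL)
    t <- c(-Inf, Inf)
  } else {
    b <- 2 * (ox * dir[1] + oy * dir[2])
    cc <- ox^2 + oy^2 - r^2
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) return(NULL)
    sq <- sqrt(disc)
    t <- sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
  }
  if (abs(dir[3]) < 1e-300) {
    if (origin[3] <= zlo || origin[3] >= zhi) return(NULL)
    tz <- c(-Inf, Inf)
  } else {
    tz <- sort(c((zlo - origin[3]) / dir[3], (zhi - origin[3]) / dir[3]))
  }
  lo <- max(t[1], tz[1]); hi <- min(t[2], tz[2])
  if (lo >= hi) return(NULL)
  c(lo, hi)
}

#' Path lengths of a ray through soil, root and internal air
#'
#' Exact ray--cylinder intersection chords. The root chord is subtracted
#' from the soil chord, so `soil + root + air` partitions the total
#' in-sample chord (internal air is zero for the packaged geometry, where
#' the root lies fully inside the soil).
#'
#' @param origin numeric length 3, mm.
#' @param direction numeric length 3, unit vector.
#' @param geometry a [sample_geometry()].
#' @param t_max optional maximum ray parameter (mm); path lengths are then
#'   measured only up to `origin + t_max * direction`. Used to integrate
#'   attenuation up to an interior point.
#' @return list with `soil`, `root` and `air` chord lengths in mm.
#' @export
ray_path_lengths <- function(origin, direction, geometry, t_max = Inf) {
  stopifnot(inherits(geometry, "sample_geometry"))
  if (abs(sum(direction^2) - 1) > 1e-9) {
    stop("direction must be a unit vector")
  }
  zs <- geometry$soil_height / 2
  soil_t <- .ray_cylinder(origin, direction, 0, 0, geometry$soil_radius,
                          -zs, zs)
  if (is.null(soil_t)) return(list(soil = 0, root = 0, air = 0))
  soil_t <- c(max(soil_t[1], 0), min(soil_t[2], t_max))
  if (soil_t[1] >= soil_t[2]) return(list(soil = 0, root = 0, air = 0))
  rc <- .root_center(geometry)
  zr <- geometry$root_height / 2
  root_t <- .ray_cylinder(origin, direction, rc[1], rc[2],
                          geometry$root_radius, -zr, zr)
  root_len <- 0
  if (!is.null(root_t)) {
    lo <- max(root_t[1], soil_t[1]); hi <- min(root_t[2], soil_t[2])
    if (lo < hi) root_len <- hi - lo
  }
  total <- soil_t[2] - soil_t[1]
  list(soil = total - root_len, root = root_len, air = 0)
}

#' Field of view of a cone beam at a given distance
#'
#' Small-angle relation `FOV = divergence * distance`; conveniently,
#' mrad times m gives mm.
#'
#' @param divergence_mrad full angular divergence, mrad.
#' @param distance_m focus-to-sample distance, m.
#' @return field-of-view edge length, mm.
#' @export
fov_at_distance <- function(divergence_mrad, distance_m) {
  if (divergence_mrad < 0 || distance_m < 0) stop("inputs must be >= 0")
  divergence_mrad * distance_m
}

#' Beam models
#'
#' Describes how the beam illuminates the sample plane. Two fluence
#' normalisations are supported: `"fov"` spreads the spectrum's total flux
#' uniformly over the field of view (exact for a focused cone beam, where
#' all photons pass through the FOV), and `"divergence_footprint"` spreads
#' it over the full beam footprint `(divergence * distance)^2` (appropriate
#' for an unfocused slit-limited source, where the imaging FOV is a detector
#' crop of a wider beam).
#'
#' @param mode `"parallel"` or `"cone"`.
#' @param fov_mm field-of-view edge length at the sample, mm.
#' @param divergence_mrad beam angular divergence, mrad.
#' @param distance_m source(or focus)-to-sample distance, m.
#' @param beamlet_mm cross-section edge of the beamlet used to define the
#'   illuminated root segment, mm.
#' @param fluence_model `"fov"` or `"divergence_footprint"`.
#' @return an object of class `beam_model`.
#' @export
beam_model <- function(mode = c("parallel", "cone"), fov_mm,
                       divergence_mrad, distance_m,
                       beamlet_mm = 0.077,
                       fluence_model = c("fov", "divergence_footprint")) {
  mode <- match.arg(mode)
  fluence_model <- match.arg(fluence_model)
  if (mode == "cone") {
    expected <- fov_at_distance(divergence_mrad, distance_m)
    if (abs(fov_mm - expected) > 0.01 * expected) {
      stop("cone beam: fov_mm must equal divergence * distance within 1%")
    }
  }
  structure(list(mode = mode, fov_mm = fov_mm,
                 divergence_mrad = divergence_mrad, distance_m = distance_m,
                 beamlet_mm = beamlet_mm, fluence_model = fluence_model),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat("<beam_model> ", x$mode, ", FOV ", x$fov_mm, " mm, ",
      x$divergence_mrad, " mrad at ", x$distance_m, " m, fluence: ",
      x$fluence_model, "\n", sep = "")
  invisible(x)
}

#' @rdname beam_model
#' @export
mogno_a_beam <- function(beamlet_mm = 0.077) {
  beam_model("parallel", fov_mm = 2.9, divergence_mrad = 0.43,
             distance_m = 22.915, beamlet_mm = beamlet_mm,
             fluence_model = "divergence_footprint")
}

#' @rdname beam_model
#' @export
mogno_b_beam <- function(distance_m, beamlet_mm = 0.077) {
  beam_model("cone", fov_mm = fov_at_distance(3.1, distance_m),
             divergence_mrad = 3.1, distance_m = distance_m,
             beamlet_mm = beamlet_mm, fluence_model = "fov")
}

# area over which the spectrum's total flux is spread, mm^2
.illuminated_area_mm2 <- function(beam) {
  switch(beam$fluence_model,
         fov = beam$fov_mm^2,
         divergence_footprint =
           (beam$divergence_mrad * beam$distance_m)^2)
}

#' Tomographic scan protocol
#'
#' @param n_projections number of projections per scan.
#' @param current_ma stored ring current, mA.
#' @param time_per_projection_s exposure time per projection, s.
#' @param full_time_s full acquisition time, s (defaults to the product;
#'   must agree with it within 10 percent).
#' @param start_angle_deg root azimuth at the start of the scan, degrees.
#' @param rotation_deg scan rotation range, degrees.
#' @param direction rotation direction (clockwise).
#' @param n_timepoints number of repeated acquisitions (timepoints).
#' @return an object of class `scan_protocol`.
#' @export
scan_protocol <- function(n_projections, current_ma, time_per_projection_s,
                          full_time_s = n_projections * time_per_projection_s,
                          start_angle_deg = 0, rotation_deg = 180,
                          direction = "cw", n_timepoints = 4) {
  if (current_ma <= 0) stop("current must be > 0")
  nominal <- n_projections * time_per_projection_s
  if (abs(full_time_s - nominal) > 0.1 * nominal) {
    stop("full_time_s differs from projections * time/projection by > 10%")
  }
  structure(list(n_projections = n_projections, current_ma = current_ma,
                 time_per_projection_s = time_per_projection_s,
                 full_time_s = full_time_s,
                 start_angle_deg = start_angle_deg %% 360,
                 rotation_deg = rotation_deg, direction = direction,
                 n_timepoints = n_timepoints),
            class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat("<scan_protocol> ", x$n_projections, " projections, ", x$current_ma,
      " mA, ", x$full_time_s, " s/scan, ", x$rotation_deg, " deg ",
      x$direction, " from ", x$start_angle_deg, " deg, ", x$n_timepoints,
      " timepoints\n", sep = "")
  invisible(x)
}
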