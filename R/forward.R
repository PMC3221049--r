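#' Spherical volume conductor
#'
#' Homogeneous conducting sphere used as the head model. All source elements
#' must lie strictly inside the sphere and all sensors outside it.
#'
#' @param sphere_centre 3-vector (mm), head-frame position of the sphere
#'   centre (the head-frame origin by convention).
#' @param sphere_radius sphere radius (mm).
#' @return An object of class `head_model`.
#' @export
head_model <- function(sphere_centre = c(0, 0, 0), sphere_radius = 90) {
  stopifnot(sphere_radius > 0)
  structure(list(sphere_centre = as.numeric(sphere_centre),
                 sphere_radius = sphere_radius), class = "head_model")
}

#' Helmet sensor array
#'
#' Quasi-uniform packing of sensors on a spherical cap (a generalized
#' Fibonacci spiral), with radial sensing orientations — the idealised
#' geometry of a whole-head axial MEG system. Axial gradiometers subtract the
#' field at an outer coil displaced by `baseline` along the sensing direction.
#'
#' @param n_channels number of sensors.
#' @param helmet_radius distance of each sensor from the cap centre (mm).
#' @param coverage_angle full opening angle of the cap (degrees).
#' @param kind `"magnetometer"` or `"axial_gradiometer"`.
#' @param baseline gradiometer baseline (mm); ignored for magnetometers.
#' @return An object of class `sensor_array` with `positions`, `orientations`,
#'   `kind`, `baseline`.
#' @export
make_helmet_array <- function(n_channels = 275, helmet_radius = 110,
                              coverage_angle = 120,
                              kind = c("magnetometer", "axial_gradiometer"),
                              baseline = 50) {
  kind <- match.arg(kind)
  stopifnot(n_channels >= 1, helmet_radius > 0,
            coverage_angle > 0, coverage_angle <= 360)
  zmin <- cos(coverage_angle / 2 * pi / 180)
  i <- seq_len(n_channels)
  z <- 1 - (1 - zmin) * (i - 0.5) / n_channels
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  structure(list(positions = helmet_radius * dirs, orientations = dirs,
                 kind = kind,
                 baseline = if (kind == "axial_gradiometer") baseline else 0),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d %s channels\n", nrow(x$positions), x$kind))
  invisible(x)
}

#' Sensor array CSV round trip
#'
#' @param sensors a [make_helmet_array()] object.
#' @param path CSV path.
#' @return `write_sensor_csv` returns `path` invisibly; `read_sensor_csv`
#'   returns a `sensor_array`.
#' @export
write_sensor_csv <- function(sensors, path) {
  df <- data.frame(x = sensors$positions[, 1], y = sensors$positions[, 2],
                   z = sensors$positions[, 3],
                   ox = sensors$orientations[, 1],
                   oy = sensors$orientations[, 2],
                   oz = sensors$orientations[, 3],
                   kind = sensors$kind, baseline = sensors$baseline)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(positions = as.matrix(df[, c("x", "y", "z")]),
                 orientations = as.matrix(df[, c("ox", "oy", "oz")]),
                 kind = df$kind[1], baseline = df$baseline[1]),
            class = "sensor_array")
}

# Radial magnetic field component is blind to volume currents, so the Sarvas
# closed form handles magnetometer and gradiometer coils alike. Geometry in
# mm, moments in nAm, fields in fT; SI conversion happens here and only here.
sarvas_field_at <- function(head, position_mm, moment_nAm, points_mm) {
  r0 <- (position_mm - head$sphere_centre) * 1e-3
  q <- moment_nAm * 1e-9
  pts <- sweep(points_mm, 2, head$sphere_centre) * 1e-3
  a <- sweep(pts, 2, r0)
  an <- row_norms(a)
  rn <- row_norms(pts)
  if (any(an < 1e-12)) stop("field point coincides with the dipole")
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  adotr <- rowSums(a * pts)
  r0dotr <- as.vector(pts %*% r0)
  # F = a (r a + r^2 - r0 . r)
  FF <- an * (rn * an + rn^2 - r0dotr)
  c1 <- an^2 / rn + adotr / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + adotr / an
  gradF <- c1 * pts - c2 * matrix(r0, nrow(pts), 3, byrow = TRUE)
  qxr0_dot_r <- as.vector(pts %*% qxr0)
  B <- 1e-7 / FF^2 * (FF * matrix(qxr0, nrow(pts), 3, byrow = TRUE) -
                        qxr0_dot_r * gradF)
  B * 1e15  # tesla -> fT
}

#' Field of a current dipole in a conducting sphere
#'
#' Sarvas closed-form magnetic field of a current dipole inside a homogeneous
#' conducting sphere (primary plus volume currents), projected on each
#' sensor's sensing direction. A dipole with a purely radial moment is silent
#' (exact zeros). For axial gradiometers the field at the outer coil
#' (displaced by the baseline along the sensing direction) is subtracted.
#'
#' @param head a [head_model()].
#' @param position 3-vector dipole position (mm), strictly inside the sphere.
#' @param moment 3-vector dipole moment (nAm).
#' @param sensors a [make_helmet_array()] object (all coils outside the
#'   sphere).
#' @return Per-channel field (fT).
#' @export
dipole_field <- function(head, position, moment, sensors) {
  if (sqrt(sum((position - head$sphere_centre)^2)) >= head$sphere_radius)
    stop("dipole must lie strictly inside the conductor sphere")
  b <- rowSums(sarvas_field_at(head, position, moment, sensors$positions) *
                 sensors$orientations)
  if (sensors$kind == "axial_gradiometer") {
    outer_pos <- sensors$positions + sensors$baseline * sensors$orientations
    b <- b - rowSums(sarvas_field_at(head, position, moment, outer_pos) *
                       sensors$orientations)
  }
  b
}

#' Unit-moment lead fields for a set of dipoles
#'
#' Convenience matrix of [dipole_field()] values for unit-moment (1 nAm)
#' dipoles at the given positions/orientations; the workhorse behind patch
#' lead fields and the surface scans.
#'
#' @param head a [head_model()].
#' @param positions k x 3 matrix (mm).
#' @param orientations k x 3 matrix of unit orientations.
#' @param sensors sensor array.
#' @return channels x k matrix (fT/nAm).
#' @export
dipole_leadfield_matrix <- function(head, positions, orientations, sensors) {
  positions <- matrix(positions, ncol = 3)
  orientations <- matrix(orientations, ncol = 3)
  out <- matrix(0, nrow(sensors$positions), nrow(positions))
  for (k in seq_len(nrow(positions)))
    out[, k] <- dipole_field(head, positions[k, ], orientations[k, ], sensors)
  out
}

#' Lead field of an extended patch source
#'
#' The patch is a single scalar source: all elements share one time course,
#' so its lead field is the moment-weighted sum of the element dipole fields
#' — this models the within-patch correlation exactly. Moments are normalised
#' to unit total, so the values are fT per nAm of total patch moment.
#'
#' @param head a [head_model()].
#' @param patch a [patch_source()]; every element must lie inside the sphere.
#' @param sensors sensor array.
#' @return An object of class `lead_field` with `values` (per-channel fT/nAm)
#'   and `source` (descriptor).
#' @export
patch_lead_field <- function(head, patch, sensors) {
  if (nrow(patch$positions) == 0L) stop("patch has no elements")
  depth <- row_norms(sweep(patch$positions, 2, head$sphere_centre))
  if (any(depth >= head$sphere_radius))
    stop("patch element outside the conductor sphere")
  w <- patch$moments
  tot <- sum(w)
  w <- if (tot > 0) w / tot else rep(1 / length(w), length(w))
  vals <- as.vector(dipole_leadfield_matrix(head, patch$positions,
                                            patch$orientations, sensors) %*% w)
  structure(list(values = vals,
                 source = list(kind = patch$kind, centre = patch$centre,
                               extent = patch$nominal_extent)),
            class = "lead_field")
}

#' Canonical-orientation disc lead fields
#'
#' Lead fields of unit-moment discs of the given radius grown perpendicular
#' to x, y and z at the same centre: the three-column basis consumed by the
#' linearised orientation solver. At radius 0 the columns are exactly the
#' Cartesian dipole lead fields.
#'
#' @param head a [head_model()].
#' @param centre 3-vector (mm).
#' @param radius disc radius (mm).
#' @param sensors sensor array.
#' @param spacing disc grid spacing (mm).
#' @return channels x 3 matrix.
#' @export
disc_basis_lead_fields <- function(head, centre, radius, sensors,
                                   spacing = 1) {
  axes <- diag(3)
  vapply(1:3, function(j) {
    patch_lead_field(head, build_disc_patch(centre, axes[j, ], radius,
                                            spacing), sensors)$values
  }, numeric(nrow(sensors$positions)))
}
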