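#' Extended patch source
#'
#' A `patch_source` is a set of elemental current dipoles (ECDs) sharing a
#' single time course: `positions` (k x 3, mm), `orientations` (k x 3, unit),
#' `moments` (k, nAm, all >= 0 in uniform mode), a `centre` (mm), a
#' `nominal_extent` (radius, mm), the patch `kind` (`"disc"` or `"cortical"`)
#' and the per-element area `element_area` (mm^2). A patch is both the
#' data-generating truth and the beamformer's source model.
#'
#' @param positions k x 3 matrix of element positions (mm).
#' @param orientations k x 3 matrix of unit element orientations.
#' @param moments length-k vector of element moments (nAm).
#' @param centre 3-vector (mm).
#' @param nominal_extent radius (mm).
#' @param kind `"disc"` or `"cortical"`.
#' @param element_area per-element area (mm^2), scalar or length-k.
#' @return An object of class `patch_source`.
#' @export
patch_source <- function(positions, orientations, moments, centre,
                         nominal_extent, kind = c("disc", "cortical"),
                         element_area = NA_real_) {
  kind <- match.arg(kind)
  positions <- matrix(as.numeric(positions), ncol = 3)
  orientations <- unit_rows(matrix(as.numeric(orientations), ncol = 3))
  stopifnot(nrow(positions) == nrow(orientations),
            length(moments) == nrow(positions))
  structure(list(positions = positions, orientations = orientations,
                 moments = as.numeric(moments), centre = as.numeric(centre),
                 nominal_extent = nominal_extent, kind = kind,
                 element_area = rep_len(element_area, nrow(positions))),
            class = "patch_source")
}

#' @export
print.patch_source <- function(x, ...) {
  cat(sprintf("patch_source (%s): %d elements, extent %.1f mm, total moment %.3g nAm\n",
              x$kind, nrow(x$positions), x$nominal_extent, sum(x$moments)))
  invisible(x)
}

orthonormal_tangents <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) c(1, 0, 0)
         else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- c(n[2] * ref[3] - n[3] * ref[2],
          n[3] * ref[1] - n[1] * ref[3],
          n[1] * ref[2] - n[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2, n = n)
}

#' Disc-shaped extended source
#'
#' Grows a square grid of elements with the given spacing in the plane through
#' `centre` perpendicular to `normal`, keeps the points within `radius` of the
#' centre (the centre element is always present, so `radius = 0` is the pure
#' dipole case), and orients every element along `normal`. Moments are uniform
#' and sum to `total_moment`.
#'
#' @param centre 3-vector (mm).
#' @param normal unit 3-vector; disc plane is perpendicular to it.
#' @param radius disc radius (mm, >= 0).
#' @param spacing grid spacing (mm).
#' @param total_moment total patch moment (nAm), split equally.
#' @return A [patch_source()] of kind `"disc"`.
#' @export
build_disc_patch <- function(centre, normal, radius, spacing = 1,
                             total_moment = 1) {
  stopifnot(radius >= 0, spacing > 0)
  b <- orthonormal_tangents(normal)
  g <- spacing * seq(-floor(radius / spacing), floor(radius / spacing))
  gg <- expand.grid(x = g, y = g)
  keep <- gg$x^2 + gg$y^2 <= radius^2 + 1e-12
  gg <- gg[keep, , drop = FALSE]
  pos <- cbind(centre[1] + gg$x * b$e1[1] + gg$y * b$e2[1],
               centre[2] + gg$x * b$e1[2] + gg$y * b$e2[2],
               centre[3] + gg$x * b$e1[3] + gg$y * b$e2[3])
  k <- nrow(pos)
  patch_source(pos, matrix(b$n, k, 3, byrow = TRUE),
               rep(total_moment / k, k), centre, radius, "disc",
               element_area = spacing^2)
}

#' Surface-following cortical patch
#'
#' Selects the mesh vertices within `geodesic_radius` of `target_vertex`
#' (distance measured along the mesh, see [geodesic_distances()]) and places
#' an element at each, oriented along the local vertex normal. Moments are
#' uniform and sum to `total_moment` (uniform current density over a
#' near-uniform mesh).
#'
#' @param mesh a [trimesh()].
#' @param target_vertex vertex index (1-based).
#' @param geodesic_radius cortical distance (mm, >= 0).
#' @param total_moment total patch moment (nAm).
#' @param distances optional precomputed geodesic distance vector from
#'   `target_vertex` (as returned by [geodesic_distances()]).
#' @return A [patch_source()] of kind `"cortical"`.
#' @export
build_cortical_patch <- function(mesh, target_vertex, geodesic_radius,
                                 total_moment = 1, distances = NULL) {
  target_vertex <- as.integer(target_vertex)
  if (target_vertex < 1L || target_vertex > nrow(mesh$vertices))
    stop("target_vertex out of range")
  stopifnot(geodesic_radius >= 0)
  d <- if (is.null(distances)) geodesic_distances(mesh, target_vertex) else distances
  members <- which(d <= geodesic_radius + 1e-12)
  k <- length(members)
  patch_source(mesh$vertices[members, , drop = FALSE],
               mesh$normals[members, , drop = FALSE],
               rep(total_moment / k, k),
               mesh$vertices[target_vertex, ],
               geodesic_radius, "cortical",
               element_area = vertex_areas(mesh)[members])
}

#' Assign element moments
#'
#' Two activation modes. `total_moment`: the total source strength Q (nAm) is
#' split equally over the elements, so the current density depends on source
#' amplitude and area. `constant_current_density`: each element carries
#' `ccd` (pAm/mm^2) times its own area, so the total moment grows with patch
#' area (1 pAm = 1e-3 nAm).
#'
#' @param patch a [patch_source()].
#' @param mode `"total_moment"` or `"constant_current_density"`.
#' @param Q total moment (nAm), for `total_moment` mode.
#' @param ccd current density (pAm/mm^2), for `constant_current_density` mode.
#' @return The patch with moments replaced.
#' @export
assign_moments <- function(patch, mode = c("total_moment",
                                           "constant_current_density"),
                           Q = NULL, ccd = NULL) {
  mode <- match.arg(mode)
  k <- nrow(patch$positions)
  if (k == 0L) stop("patch has no elements")
  if (mode == "total_moment") {
    if (is.null(Q) || Q < 0) stop("total_moment mode needs Q >= 0 (nAm)")
    patch$moments <- rep(Q / k, k)
  } else {
    if (is.null(ccd) || ccd < 0)
      stop("constant_current_density mode needs ccd >= 0 (pAm/mm^2)")
    if (anyNA(patch$element_area)) stop("patch has no element areas")
    patch$moments <- ccd * 1e-3 * patch$element_area
  }
  patch
}

#' Patch curvature metric (degrees)
#'
#' The average change in orientation across a patch: the mean angle between
#' each element orientation and the patch's mean orientation (the renormalised
#' mean of the element unit normals). A flat patch scores 0; a patch whose
#' mean normal is degenerate (normals cancelling, norm < 1e-9) is flagged as
#' maximally curved (90 degrees).
#'
#' @param patch a [patch_source()].
#' @return Curvature in degrees.
#' @export
patch_curvature <- function(patch) {
  if (nrow(patch$positions) < 1L) stop("patch has no elements")
  m <- colMeans(patch$orientations)
  len <- sqrt(sum(m^2))
  if (len < 1e-9) return(90)
  m <- m / len
  cosang <- pmin(1, pmax(-1, as.vector(patch$orientations %*% m)))
  mean(acos(cosang)) * 180 / pi
}

#' Median-split curvature classification
#'
#' Labels each patch `"curved"` when its [patch_curvature()] exceeds the
#' median over all patches, and `"flat"` otherwise (ties, including the
#' all-equal case, go to `"flat"`). With an even number of distinct
#' curvatures this yields an exact half split.
#'
#' @param patches a list of [patch_source()] objects, or a numeric vector of
#'   curvature values.
#' @return Character vector of `"curved"` / `"flat"` labels.
#' @export
classify_curvature <- function(patches) {
  curv <- if (is.numeric(patches)) patches
          else vapply(patches, patch_curvature, numeric(1))
  if (length(curv) < 2L) stop("need at least two patches for a median split")
  ifelse(curv > stats::median(curv), "curved", "flat")
}

#' Export a patch as a plain table
#'
#' @param patch a [patch_source()].
#' @param path optional CSV path; when given the table is written there.
#' @return A data.frame with element position, orientation and moment.
#' @export
patch_table <- function(patch, path = NULL) {
  df <- data.frame(x = patch$positions[, 1], y = patch$positions[, 2],
                   z = patch$positions[, 3], nx = patch$orientations[, 1],
                   ny = patch$orientations[, 2], nz = patch$orientations[, 3],
                   moment_nAm = patch$moments)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
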