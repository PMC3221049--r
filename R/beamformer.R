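#' Sample covariance of an analysis window
#'
#' Channel covariance pooled over every epoch and sample of the window, with
#' the pooled channel means removed. No regularisation is applied at any
#' point: a singular covariance is surfaced as an error by the weight solver,
#' never silently fixed.
#'
#' @param window an `epoch_data` object.
#' @return An object of class `covariance_estimate` with `matrix` (channels x
#'   channels, fT^2), `n_samples_used` and `window_label`.
#' @export
estimate_covariance <- function(window) {
  d <- dim(window$samples)
  m <- matrix(window$samples, nrow = d[1] * d[2], ncol = d[3])
  m <- sweep(m, 2, colMeans(m))
  structure(list(matrix = crossprod(m) / nrow(m), n_samples_used = nrow(m),
                 window_label = window$window_label),
            class = "covariance_estimate")
}

cov_matrix <- function(C) if (inherits(C, "covariance_estimate")) C$matrix else C

solve_cov <- function(C) {
  tryCatch(solve(cov_matrix(C)),
           error = function(e) stop(
             "covariance matrix is singular; regularisation is intentionally ",
             "not applied - collect more samples or reduce channels",
             call. = FALSE))
}

#' Minimum-variance beamformer weights
#'
#' The unit-gain distortionless solution `w = C^-1 l / (l' C^-1 l)`: among all
#' weight vectors passing the model lead field with gain 1, it minimises the
#' output variance `w' C w`.
#'
#' @param C a `covariance_estimate` or plain matrix.
#' @param l model lead field (per-channel vector or `lead_field`).
#' @return Per-channel weight vector satisfying `sum(w * l) == 1`.
#' @export
beamformer_weights <- function(C, l) {
  l <- if (inherits(l, "lead_field")) l$values else as.numeric(l)
  if (all(l == 0)) stop("lead field is identically zero")
  Cil <- solve_cov(C) %*% l
  g <- sum(l * Cil)
  if (!is.finite(g) || g <= 0) stop("degenerate lead field / covariance pair")
  w <- as.vector(Cil) / g
  stopifnot(abs(sum(w * l) - 1) < 1e-6)
  w
}

#' Pseudo-Z beamformer output
#'
#' Projected source power normalised by the intrinsic channel noise projected
#' through the same weights: `(w' C w) / (sigma2 * w' w)`. Invariant to
#' rescaling of the weights; approximately 1 on pure white noise of variance
#' `sigma2`.
#'
#' @param weights per-channel weights.
#' @param C a `covariance_estimate` or matrix.
#' @param noise_variance per-channel white-noise variance sigma2 (fT^2),
#'   e.g. [white_noise_variance()].
#' @return Dimensionless pseudo-Z.
#' @export
pseudo_z <- function(weights, C, noise_variance) {
  stopifnot(noise_variance > 0)
  if (all(weights == 0)) stop("weights are identically zero")
  as.numeric(crossprod(weights, cov_matrix(C) %*% weights)) /
    (noise_variance * sum(weights^2))
}

# closed form equivalent to beamformer_weights + pseudo_z, used on hot paths:
# pz = (l' Ci l) / (sigma2 * l' Ci^2 l)
pseudo_z_closed <- function(Ci, l, noise_variance) {
  u <- Ci %*% l
  as.numeric(crossprod(l, u)) / (noise_variance * sum(u^2))
}

#' Linearised (Sekihara) orientation solver
#'
#' Treats the model lead field as linear in the orientation, `l(u) = L u`,
#' with `L` the three canonical-orientation disc lead fields
#' ([disc_basis_lead_fields()]), and returns the generalized eigenvector
#' maximising `(u' L'C^-1 L u) / (u' L'C^-2 L u)` — that ratio is the
#' pseudo-Z of `L u` up to the noise variance, so this is the orientation
#' maximising the beamformer output under the linearity assumption. The assumption is exact for a
#' point source; for a large disc, physically re-growing the disc moves its
#' elements, which this solver ignores (see [orientation_spinning()]).
#' Near-silent basis directions (e.g. the radial direction of a point source
#' in a sphere) are projected out before solving.
#'
#' @param C a `covariance_estimate` or matrix.
#' @param basis channels x 3 matrix of canonical-orientation lead fields.
#' @return Unit 3-vector, sign fixed so its first non-zero component is
#'   positive.
#' @export
orientation_sekihara <- function(C, basis) {
  Ci <- solve_cov(C)
  sv <- svd(basis)
  # a direction whose disc lead field is < 1e-3 of the dominant one is
  # treated as silent (e.g. the radial direction in a spherical conductor):
  # the pseudo-Z is scale-invariant, so without this guard the solver can
  # lock onto the numerical-noise pattern of a silent direction
  keep <- sv$d > 1e-3 * sv$d[1]
  if (!any(keep)) stop("orientation eigenproblem is degenerate (silent basis)")
  Lr <- basis %*% sv$v[, keep, drop = FALSE]
  CiL <- Ci %*% Lr
  A <- crossprod(Lr, CiL)
  B <- crossprod(CiL)
  R <- tryCatch(chol(B), error = function(e)
    stop("orientation eigenproblem is degenerate", call. = FALSE))
  Ri <- backsolve(R, diag(ncol(R)))
  M <- t(Ri) %*% A %*% Ri
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  # largest generalized eigenvalue: the ratio being maximised is exactly the
  # pseudo-Z of l(u) = L u (up to the constant noise variance)
  w <- Ri %*% e$vectors[, 1]
  u <- as.vector(sv$v[, keep, drop = FALSE] %*% w)
  u <- u / sqrt(sum(u^2))
  fix_sign(u)
}

fix_sign <- function(u) {
  j <- which(abs(u) > 1e-12)[1]
  if (!is.na(j) && u[j] < 0) -u else u
}

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Exhaustive ("spinning") orientation search
#'
#' Physically re-grows the disc model perpendicular to each direction of a
#' quasi-uniform hemisphere grid, evaluates the pseudo-Z, and refines around
#' the best direction with a local simplex search. Unlike the linearised
#' solver this accounts for the element displacement that rotating an
#' extended disc entails, at much higher cost.
#'
#' @param C a `covariance_estimate` or matrix.
#' @param head a [head_model()].
#' @param sensors sensor array.
#' @param centre disc centre (mm).
#' @param radius disc radius (mm).
#' @param noise_variance sigma2 (fT^2).
#' @param n_directions hemisphere grid size (>= 20).
#' @param spacing disc grid spacing (mm).
#' @return Unit 3-vector (sign-fixed), with attribute `"pseudo_z"`.
#' @export
orientation_spinning <- function(C, head, sensors, centre, radius,
                                 noise_variance, n_directions = 200,
                                 spacing = 1) {
  stopifnot(n_directions >= 20)
  Ci <- solve_cov(C)
  pz_of_dir <- function(u) {
    u <- u / sqrt(sum(u^2))
    lf <- patch_lead_field(head, build_disc_patch(centre, u, radius, spacing),
                           sensors)$values
    pseudo_z_closed(Ci, lf, noise_variance)
  }
  dirs <- fibonacci_hemisphere(n_directions)
  pz <- apply(dirs, 1, pz_of_dir)
  best <- dirs[which.max(pz), ]
  tg <- orthonormal_tangents(best)
  obj <- function(ab) -pz_of_dir(best + ab[1] * tg$e1 + ab[2] * tg$e2)
  opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 50, reltol = 1e-6))
  u <- best + opt$par[1] * tg$e1 + opt$par[2] * tg$e2
  u <- fix_sign(u / sqrt(sum(u^2)))
  attr(u, "pseudo_z") <- -opt$value
  u
}

new_scan_result <- function(radii, pz, centres, truth_centre) {
  i <- which.max(pz)  # ties resolve to the smallest radius (radii sorted)
  est_centre <- centres[i, ]
  structure(list(radii = radii, pseudo_z = pz, centres = centres,
                 estimated_extent = radii[i], estimated_centre = est_centre,
                 localisation_error = if (is.null(truth_centre)) NA_real_
                                      else sqrt(sum((est_centre - truth_centre)^2)),
                 peak_pseudo_z = pz[i],
                 flat_curve = (max(pz) - min(pz)) < 0.05 * abs(max(pz))),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: estimated extent %.1f mm (pseudo-Z %.2f), localisation error %.2f mm%s\n",
              x$estimated_extent, x$peak_pseudo_z, x$localisation_error,
              if (isTRUE(x$flat_curve)) " [flat curve - low confidence]" else ""))
  invisible(x)
}

#' @export
as.data.frame.scan_result <- function(x, ...) {
  data.frame(radius_mm = x$radii, pseudo_z = x$pseudo_z,
             centre_x = x$centres[, 1], centre_y = x$centres[, 2],
             centre_z = x$centres[, 3])
}

#' Radius scan: extent estimation by model scanning
#'
#' Evaluates the beamformer output for source models of increasing radius and
#' takes the argmax as the estimated spatial extent. `model_generator` is
#' called once per radius with `(radius, C, Ci)` and must return
#' `list(lead_field = <per-channel vector>, centre = <3-vector>)`; this is
#' where the orientation solver and position strategy of the concrete model
#' live (see [scan_disc_extent()] and [scan_cortical_extent()]). Ties in the
#' pseudo-Z curve resolve to the smallest radius (parsimony), and a curve
#' that is flat to within 5% is flagged as low-confidence.
#'
#' @param window an `epoch_data` object (or a precomputed
#'   `covariance_estimate`).
#' @param model_generator function of `(radius, C, Ci)`.
#' @param radii sorted non-empty vector of model radii (mm).
#' @param noise_variance sigma2 (fT^2) for the pseudo-Z.
#' @param truth_centre optional generating-source centre for the localisation
#'   error.
#' @return A `scan_result`.
#' @export
radius_scan <- function(window, model_generator, radii, noise_variance,
                        truth_centre = NULL) {
  if (length(radii) == 0L || is.unsorted(radii)) stop("radii must be sorted and non-empty")
  C <- if (inherits(window, "covariance_estimate")) window else estimate_covariance(window)
  Ci <- solve_cov(C)
  pz <- numeric(length(radii))
  centres <- matrix(NA_real_, length(radii), 3)
  for (i in seq_along(radii)) {
    mod <- model_generator(radii[i], C, Ci)
    w <- beamformer_weights(C, mod$lead_field)
    pz[i] <- pseudo_z(w, C, noise_variance)
    centres[i, ] <- mod$centre
  }
  new_scan_result(radii, pz, centres, truth_centre)
}

#' Nonlinear position optimisation of an extended model
#'
#' Derivative-free simplex search over the 3-vector model centre maximising
#' the pseudo-Z of a disc model of the given radius, starting from
#' `init_centre` (conventionally the known target location). The orientation solver is re-run at every candidate position.
#' Candidates leaving the conductor sphere are penalised; a best point
#' clipped at the boundary is flagged.
#'
#' @param C a `covariance_estimate` or matrix.
#' @param head,sensors forward-model geometry.
#' @param radius model disc radius (mm).
#' @param init_centre starting centre (mm), inside the conductor.
#' @param noise_variance sigma2 (fT^2).
#' @param orientation `"sekihara"` or `"spinning"`.
#' @param spacing disc grid spacing (mm).
#' @param max_evaluations simplex evaluation budget.
#' @return 3-vector centre with attributes `"pseudo_z"` and `"clipped"`.
#' @export
optimise_position <- function(C, head, sensors, radius, init_centre,
                              noise_variance, orientation = "sekihara",
                              spacing = 1, max_evaluations = 200) {
  margin <- head$sphere_radius - radius - 1
  if (sqrt(sum((init_centre - head$sphere_centre)^2)) >= margin)
    stop("init_centre too close to the conductor boundary")
  Ci <- solve_cov(C)
  clipped <- FALSE
  obj <- function(cen) {
    if (sqrt(sum((cen - head$sphere_centre)^2)) >= margin) {
      clipped <<- TRUE
      return(1e6)
    }
    lf <- disc_model_leadfield(cov_matrix(C), Ci, head, sensors, cen, radius,
                               noise_variance, orientation, spacing)
    -pseudo_z_closed(Ci, lf$lead_field, noise_variance)
  }
  opt <- stats::optim(init_centre, obj, method = "Nelder-Mead",
                      control = list(maxit = max_evaluations, reltol = 1e-6))
  out <- opt$par
  attr(out, "pseudo_z") <- -opt$value
  attr(out, "clipped") <- clipped
  out
}

disc_model_leadfield <- function(C, Ci, head, sensors, centre, radius,
                                 noise_variance, orientation, spacing,
                                 n_directions = 200) {
  u <- if (orientation == "spinning")
    orientation_spinning(C, head, sensors, centre, radius, noise_variance,
                         n_directions, spacing)
  else
    orientation_sekihara(C, disc_basis_lead_fields(head, centre, radius,
                                                   sensors, spacing))
  lf <- patch_lead_field(head, build_disc_patch(centre, u, radius, spacing),
                         sensors)$values
  list(lead_field = lf, orientation = as.vector(u))
}

#' Disc-model extent scan
#'
#' [radius_scan()] specialised to disc-shaped models: per radius the disc
#' orientation is solved (linearised or spinning search) and the centre is
#' either held at the supplied (correct) location or optimised by simplex
#' search initialised there.
#'
#' @param window `epoch_data` or `covariance_estimate`.
#' @param head,sensors forward-model geometry.
#' @param centre target (correct) source location (mm).
#' @param radii model radii (mm), sorted.
#' @param noise_variance sigma2 (fT^2).
#' @param orientation `"sekihara"` (default) or `"spinning"`.
#' @param position `"fixed"` (default) or `"optimise"`.
#' @param spacing disc grid spacing (mm).
#' @param truth_centre generating centre for the localisation error
#'   (defaults to `centre`).
#' @param n_directions spinning grid size.
#' @return A `scan_result`.
#' @export
scan_disc_extent <- function(window, head, sensors, centre, radii,
                             noise_variance,
                             orientation = c("sekihara", "spinning"),
                             position = c("fixed", "optimise"), spacing = 1,
                             truth_centre = centre, n_directions = 200) {
  orientation <- match.arg(orientation)
  position <- match.arg(position)
  gen <- function(radius, C, Ci) {
    cen <- centre
    if (position == "optimise")
      cen <- as.vector(optimise_position(C, head, sensors, radius, centre,
                                         noise_variance, orientation, spacing))
    mod <- disc_model_leadfield(cov_matrix(C), Ci, head, sensors, cen, radius,
                                noise_variance, orientation, spacing,
                                n_directions)
    list(lead_field = mod$lead_field, centre = cen)
  }
  radius_scan(window, gen, radii, noise_variance, truth_centre)
}

#' Precomputation for cortical-model scans
#'
#' Caches, for one target vertex, the candidate centre set (all vertices
#' within `max_distance` Euclidean of the target), the geodesic distances
#' from every candidate, and the per-vertex unit dipole lead fields over the
#' membership universe. Makes repeated [scan_cortical_extent()] calls on the
#' same geometry cheap.
#'
#' @param mesh a [trimesh()] (the beamformer's model surface, possibly
#'   shifted).
#' @param target_vertex index of the target vertex on `mesh`.
#' @param head,sensors forward-model geometry.
#' @param max_distance candidate radius (mm); use 0 for the fixed-position
#'   strategy.
#' @param max_radius largest model radius the cache must support (mm).
#' @param radii optional model radii; when given, the per-candidate patch
#'   lead fields are additionally precomputed per radius (they depend only
#'   on geometry), which makes scanning many windows over the same source
#'   much faster.
#' @return An opaque list consumed by [scan_cortical_extent()].
#' @export
precompute_cortical_scan <- function(mesh, target_vertex, head, sensors,
                                     max_distance = 25, max_radius = 20,
                                     radii = NULL) {
  target_vertex <- as.integer(target_vertex)
  pos_t <- mesh$vertices[target_vertex, ]
  eu <- row_norms(sweep(mesh$vertices, 2, pos_t))
  cand <- which(eu <= max_distance + 1e-9)
  if (length(cand) == 0L) stop("empty candidate set")
  universe <- which(eu <= max_distance + max_radius + 5)
  gd <- geodesic_distances(mesh, cand)
  gd <- matrix(gd, nrow = length(cand))[, universe, drop = FALSE]
  L <- dipole_leadfield_matrix(head, mesh$vertices[universe, , drop = FALSE],
                               mesh$normals[universe, , drop = FALSE], sensors)
  pre <- list(mesh = mesh, target_vertex = target_vertex,
              target_position = pos_t, candidates = cand,
              candidate_positions = mesh$vertices[cand, , drop = FALSE],
              universe = universe, geodesic = gd, leadfields = L,
              cand_euclid = eu[cand])
  if (!is.null(radii)) {
    pre$patch_leadfields <- lapply(radii, function(r)
      candidate_patch_leadfields(pre, r))
    names(pre$patch_leadfields) <- format(radii)
  }
  pre
}

# unit-total-moment lead fields of the geodesic patch centred at every
# candidate, as a dense channels x candidates matrix
candidate_patch_leadfields <- function(pre, radius) {
  hits <- which(pre$geodesic <= radius + 1e-12, arr.ind = TRUE)
  nmem <- tabulate(hits[, 1], nbins = length(pre$candidates))
  M <- Matrix::sparseMatrix(i = hits[, 2], j = hits[, 1],
                            x = 1 / nmem[hits[, 1]],
                            dims = c(length(pre$universe),
                                     length(pre$candidates)))
  as.matrix(pre$leadfields %*% M)
}

#' Constrained vertex scan at one model radius
#'
#' Evaluates the pseudo-Z of cortical patches (geodesic radius `radius`,
#' elements oriented along local normals) centred at every candidate vertex,
#' and returns the argmax; ties resolve to the candidate nearest the target.
#' This is the surface-constrained position strategy: only cortical elements
#' within the candidate distance of the target are considered as possible
#' patch centres.
#'
#' @param pre a [precompute_cortical_scan()] cache.
#' @param C a `covariance_estimate` or matrix.
#' @param radius model geodesic radius (mm).
#' @param noise_variance sigma2 (fT^2).
#' @param Ci optional precomputed inverse covariance.
#' @return list with `vertex` (index into the mesh), `pseudo_z` (at the
#'   argmax), `centre`, and the per-candidate `values`.
#' @export
constrained_vertex_scan <- function(pre, C, radius, noise_variance, Ci = NULL) {
  if (is.null(Ci)) Ci <- solve_cov(C)
  key <- format(radius)
  Lp <- if (!is.null(pre$patch_leadfields[[key]])) pre$patch_leadfields[[key]]
        else candidate_patch_leadfields(pre, radius)
  U <- Ci %*% Lp
  pz <- colSums(Lp * U) / (noise_variance * colSums(U * U))
  best <- which(pz == max(pz))
  if (length(best) > 1L) best <- best[which.min(pre$cand_euclid[best])]
  list(vertex = pre$candidates[best], pseudo_z = pz[best],
       centre = pre$candidate_positions[best, ], values = pz,
       lead_field = Lp[, best])
}

#' Cortical-model extent scan
#'
#' [radius_scan()] specialised to surface-following patch models: per radius
#' the model is a geodesic patch on the (possibly shifted) model surface with
#' fixed local-normal element orientations, and the centre is either the
#' target vertex (`"fixed"`) or the best of all candidate vertices within
#' `max_distance` of the target (`"constrained"`).
#'
#' @param window `epoch_data` or `covariance_estimate`.
#' @param pre a [precompute_cortical_scan()] cache (built with
#'   `max_distance = 0` for the fixed strategy).
#' @param radii model geodesic radii (mm), sorted.
#' @param noise_variance sigma2 (fT^2).
#' @param truth_centre generating-source centre (mm) for the localisation
#'   error.
#' @return A `scan_result`.
#' @export
scan_cortical_extent <- function(window, pre, radii, noise_variance,
                                 truth_centre = NULL) {
  if (length(radii) == 0L || is.unsorted(radii)) stop("radii must be sorted and non-empty")
  C <- if (inherits(window, "covariance_estimate")) window else estimate_covariance(window)
  Ci <- solve_cov(C)
  pz <- numeric(length(radii))
  centres <- matrix(NA_real_, length(radii), 3)
  for (i in seq_along(radii)) {
    sc <- constrained_vertex_scan(pre, C, radii[i], noise_variance, Ci)
    pz[i] <- sc$pseudo_z
    centres[i, ] <- sc$centre
  }
  new_scan_result(radii, pz, centres, truth_centre)
}
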