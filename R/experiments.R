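#' Experiment configuration
#'
#' Validated configuration for [run_extent_experiment()]. The defaults are a
#' desk-scale version of the full simulation study: a 120-channel helmet, an
#' 80 mm folded sheet at 1 mm spacing, model radii 0-20 mm in 2 mm steps and
#' 3 noise realisations. Identical configuration plus seed gives identical
#' outputs.
#'
#' @param truth_kind `"cortical"` (surface-following truth patches) or
#'   `"disc"`.
#' @param model_kind beamformer model: `"matched"` (same kind as the truth),
#'   `"disc"`, or `"cortical"`.
#' @param n_sources number of target sources (cortical truth).
#' @param true_extents generating-source extents (mm).
#' @param Q source strength used for reporting (nAm).
#' @param radii model radii scanned (mm).
#' @param n_seeds noise realisations per condition.
#' @param shifts rigid surface-shift magnitudes applied to the model surface
#'   (mm); data always come from the unshifted surface.
#' @param position `"fixed"`, `"optimise"` (disc models) or `"constrained"`
#'   (cortical models).
#' @param max_distance candidate radius for the constrained strategy (mm).
#' @param orientation disc orientation solver, `"sekihara"` or `"spinning"`.
#' @param moment_mode `"total_moment"` or `"constant_current_density"`.
#' @param ccd current density (pAm/mm^2) for constant-current-density mode.
#' @param mesh_extent,fold_amplitude,fold_wavelength,target_spacing,cap_radius
#'   synthetic-cortex parameters, see [make_synthetic_cortex()].
#' @param mesh_centre sheet centre in the head frame (mm).
#' @param n_channels,helmet_radius,coverage_angle,sensor_kind helmet
#'   parameters, see [make_helmet_array()].
#' @param sphere_radius conductor radius (mm).
#' @param noise a [noise_spec()].
#' @param disc_centre,disc_orientation truth geometry for disc truth.
#' @param seed master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(truth_kind = c("cortical", "disc"),
                              model_kind = c("matched", "disc", "cortical"),
                              n_sources = 6,
                              true_extents = seq(0, 18, by = 3),
                              Q = 20,
                              radii = seq(0, 20, by = 2),
                              n_seeds = 3,
                              shifts = 0,
                              position = c("fixed", "optimise", "constrained"),
                              max_distance = 25,
                              orientation = c("sekihara", "spinning"),
                              moment_mode = c("total_moment",
                                              "constant_current_density"),
                              ccd = 50,
                              mesh_extent = 80, fold_amplitude = 3,
                              fold_wavelength = 25, target_spacing = 1,
                              cap_radius = 200, mesh_centre = c(0, 0, 65),
                              n_channels = 120, helmet_radius = 110,
                              coverage_angle = 120,
                              sensor_kind = "magnetometer",
                              sphere_radius = 90,
                              noise = noise_spec(),
                              disc_centre = c(0, 0, 65),
                              disc_orientation = c(1, 0, 0),
                              seed = 1L) {
  cfg <- list(truth_kind = match.arg(truth_kind),
              model_kind = match.arg(model_kind),
              n_sources = n_sources, true_extents = sort(true_extents),
              Q = Q, radii = sort(radii), n_seeds = n_seeds,
              shifts = shifts, position = match.arg(position),
              max_distance = max_distance,
              orientation = match.arg(orientation),
              moment_mode = match.arg(moment_mode), ccd = ccd,
              mesh_extent = mesh_extent, fold_amplitude = fold_amplitude,
              fold_wavelength = fold_wavelength,
              target_spacing = target_spacing, cap_radius = cap_radius,
              mesh_centre = mesh_centre, n_channels = n_channels,
              helmet_radius = helmet_radius,
              coverage_angle = coverage_angle, sensor_kind = sensor_kind,
              sphere_radius = sphere_radius, noise = noise,
              disc_centre = disc_centre,
              disc_orientation = disc_orientation,
              seed = as.integer(seed))
  if (cfg$model_kind == "matched") cfg$model_kind <- cfg$truth_kind
  if (cfg$truth_kind == "disc" && cfg$model_kind == "cortical")
    stop("cortical models for disc truth are not supported")
  if (cfg$position == "constrained" && cfg$model_kind != "cortical")
    stop("the constrained strategy applies to cortical models only")
  if (cfg$n_seeds < 1 || cfg$n_sources < 1) stop("n_seeds and n_sources must be >= 1")
  structure(cfg, class = "experiment_config")
}

cell_seed <- function(master, ...) {
  idx <- c(...)
  as.integer((master * 1009 + sum(idx * (7919 + seq_along(idx)))) %% 2100000000)
}

#' Pick well-separated target vertices on a mesh
#'
#' Farthest-point sampling over the interior of the sheet (seeded start),
#' giving deterministically spread target sources.
#'
#' @param mesh a [trimesh()].
#' @param n number of targets.
#' @param seed integer seed.
#' @param margin keep targets at least this Euclidean distance inside the
#'   sheet boundary (mm).
#' @return Integer vector of vertex indices.
#' @export
pick_target_vertices <- function(mesh, n, seed = 1L, margin = 10) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  rad <- max(row_norms(sweep(v, 2, ctr)))
  interior <- which(row_norms(sweep(v, 2, ctr)) <= rad - margin)
  if (length(interior) < n) stop("not enough interior vertices")
  set.seed(as.integer(seed))
  picks <- interior[sample.int(length(interior), 1)]
  while (length(picks) < n) {
    d <- sapply(picks, function(p)
      row_norms(sweep(v[interior, , drop = FALSE], 2, v[p, ])))
    picks <- c(picks, interior[which.max(apply(d, 1, min))])
  }
  picks
}

#' Run the extent-recovery experiment
#'
#' The full simulation loop: for every target source, surface shift, true
#' extent and noise seed, simulate an analysis window (plus its Q = 0 noise
#' reference), run the radius scan with the configured model, and record one
#' row. Errors in individual cells are caught and recorded; the run
#' continues. Co-registration error is emulated by shifting the model
#' surface only.
#'
#' @param config an [experiment_config()].
#' @param progress print per-source progress lines.
#' @return A data.frame (the extent table): source, curvature label, true
#'   extent, Q, shift, seed, estimated extent, pseudo-Z, localisation error
#'   and SNR, one row per evaluated condition.
#' @export
run_extent_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  head <- head_model(sphere_radius = config$sphere_radius)
  sensors <- make_helmet_array(config$n_channels, config$helmet_radius,
                               config$coverage_angle, config$sensor_kind)
  sigma2 <- white_noise_variance(config$noise)
  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)

  if (config$truth_kind == "disc") {
    for (ext_i in seq_along(config$true_extents)) {
      ext <- config$true_extents[ext_i]
      truth <- build_disc_patch(config$disc_centre, config$disc_orientation,
                                ext)
      lf <- patch_lead_field(head, truth, sensors)
      Qe <- effective_Q(config, truth)
      for (s in seq_len(config$n_seeds)) {
        w0 <- simulate_window(lf, 0, config$noise,
                              seed = cell_seed(config$seed, ext_i, s, 1))
        wq <- simulate_window(lf, Qe, config$noise,
                              seed = cell_seed(config$seed, ext_i, s, 2))
        res <- try(scan_disc_extent(wq, head, sensors, config$disc_centre,
                                    config$radii, sigma2,
                                    orientation = config$orientation,
                                    position = if (config$position == "optimise")
                                      "optimise" else "fixed"),
                   silent = TRUE)
        add_row(source = 1L, label = "disc", true_extent = ext, Q = Qe,
                shift = 0, seed = s,
                estimated_extent = if (inherits(res, "try-error")) NA_real_
                                   else res$estimated_extent,
                pseudo_z = if (inherits(res, "try-error")) NA_real_
                           else res$peak_pseudo_z,
                localisation_error = if (inherits(res, "try-error")) NA_real_
                                     else res$localisation_error,
                snr = estimate_snr(wq, w0),
                error = if (inherits(res, "try-error"))
                  conditionMessage(attr(res, "condition")) else "")
      }
      if (progress) message(sprintf("disc extent %g mm done", ext))
    }
    return(do.call(rbind, rows))
  }

  mesh <- make_synthetic_cortex(config$mesh_extent, config$fold_amplitude,
                                config$fold_wavelength,
                                config$target_spacing,
                                seed = config$seed, cap_radius = config$cap_radius,
                                centre = config$mesh_centre)
  targets <- pick_target_vertices(mesh, config$n_sources, seed = config$seed)
  gd_truth <- geodesic_distances(mesh, targets)
  gd_truth <- matrix(gd_truth, nrow = length(targets))
  curv <- vapply(seq_along(targets), function(i)
    patch_curvature(build_cortical_patch(mesh, targets[i], 10,
                                         distances = gd_truth[i, ])),
    numeric(1))
  labels <- classify_curvature(curv)

  for (sh_i in seq_along(config$shifts)) {
    sh <- config$shifts[sh_i]
    model_mesh <- if (sh > 0)
      shift_mesh(mesh, sh, direction_seed = cell_seed(config$seed, sh_i))
    else mesh
    for (src_i in seq_along(targets)) {
      tv <- targets[src_i]
      truth10 <- NULL
      pre <- if (config$model_kind == "cortical")
        precompute_cortical_scan(model_mesh, tv, head, sensors,
                                 max_distance = if (config$position ==
                                                    "constrained")
                                   config$max_distance else 0,
                                 max_radius = max(config$radii),
                                 radii = config$radii)
      else NULL
      for (ext_i in seq_along(config$true_extents)) {
        ext <- config$true_extents[ext_i]
        truth <- build_cortical_patch(mesh, tv, ext,
                                      distances = gd_truth[src_i, ])
        lf <- patch_lead_field(head, truth, sensors)
        Qe <- effective_Q(config, truth)
        for (s in seq_len(config$n_seeds)) {
          w0 <- simulate_window(lf, 0, config$noise,
                                seed = cell_seed(config$seed, sh_i, src_i,
                                                 ext_i, s, 1))
          wq <- simulate_window(lf, Qe, config$noise,
                                seed = cell_seed(config$seed, sh_i, src_i,
                                                 ext_i, s, 2))
          res <- try({
            if (config$model_kind == "cortical")
              scan_cortical_extent(wq, pre, config$radii, sigma2,
                                   truth_centre = mesh$vertices[tv, ])
            else
              scan_disc_extent(wq, head, sensors, mesh$vertices[tv, ],
                               config$radii, sigma2,
                               orientation = config$orientation,
                               position = if (config$position == "optimise")
                                 "optimise" else "fixed")
          }, silent = TRUE)
          add_row(source = src_i, label = labels[src_i], true_extent = ext,
                  Q = Qe, shift = sh, seed = s,
                  estimated_extent = if (inherits(res, "try-error")) NA_real_
                                     else res$estimated_extent,
                  pseudo_z = if (inherits(res, "try-error")) NA_real_
                             else res$peak_pseudo_z,
                  localisation_error = if (inherits(res, "try-error"))
                    NA_real_ else res$localisation_error,
                  snr = estimate_snr(wq, w0),
                  error = if (inherits(res, "try-error"))
                    conditionMessage(attr(res, "condition")) else "")
        }
      }
      if (progress)
        message(sprintf("shift %g mm: source %d/%d (%s) done", sh, src_i,
                        length(targets), labels[src_i]))
    }
  }
  do.call(rbind, rows)
}

effective_Q <- function(config, truth) {
  if (config$moment_mode == "total_moment") return(config$Q)
  sum(assign_moments(truth, "constant_current_density",
                     ccd = config$ccd)$moments)
}

#' Least-squares fit of estimated on true extent
#'
#' Ordinary least squares through the (true extent, estimated extent) points
#' of one source, as used to summarise whether a source's estimated extent
#' tracks its true extent.
#'
#' @param true_extent,estimated_extent numeric vectors, or a data.frame with
#'   columns of those names passed as the first argument.
#' @return list with `slope`, `intercept`, `r_squared`, `f_statistic`
#'   (slope != 0), `df` and `n`.
#' @export
fit_extent_regression <- function(true_extent, estimated_extent = NULL) {
  if (is.data.frame(true_extent)) {
    estimated_extent <- true_extent$estimated_extent
    true_extent <- true_extent$true_extent
  }
  ok <- is.finite(true_extent) & is.finite(estimated_extent)
  x <- true_extent[ok]; y <- estimated_extent[ok]
  if (length(x) < 3) stop("need at least 3 points for a regression")
  if (stats::var(x) == 0) stop("true extent has zero variance; fit undefined")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       f_statistic = unname(sm$fstatistic[1]),
       df = unname(sm$fstatistic[3]),
       n = length(x))
}

#' Two-sample t statistic from summary statistics
#'
#' Pooled-variance two-sample t from group means, standard deviations and
#' sizes, with `n1 + n2 - 2` degrees of freedom; reproduces caption-level
#' comparisons of regression gradients between source groups.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df` and two-sided `p_value`.
#' @export
two_sample_t_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) {
    if (mean1 == mean2) 0 else stop("zero pooled variance with unequal means")
  } else (mean1 - mean2) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' One-tailed exact binomial tail probability
#'
#' Exact upper-tail probability P(X >= k) for X ~ Binomial(n, p0); used to
#' test whether the number of sources showing a positive extent relationship
#' exceeds chance.
#'
#' @param k_successes observed successes (0..n).
#' @param n trials.
#' @param p0 null success probability.
#' @return Tail probability.
#' @export
binomial_one_tailed <- function(k_successes, n, p0 = 0.5) {
  stopifnot(k_successes >= 0, k_successes <= n)
  if (k_successes == 0) return(1)
  stats::pbinom(k_successes - 1, n, p0, lower.tail = FALSE)
}

#' Summarise an extent table into per-source regressions and group contrasts
#'
#' Fits [fit_extent_regression()] per source (pooling noise realisations)
#' within each shift level, then contrasts the mean regression gradient of
#' flat versus curved sources with [two_sample_t_from_summaries()] and counts
#' sources with a positive gradient against chance with
#' [binomial_one_tailed()].
#'
#' @param tbl an extent table from [run_extent_experiment()].
#' @return list with `per_source` (data.frame of slopes) and `contrasts`
#'   (data.frame per shift: group means/sds, t, df, binomial p).
#' @export
report_extent_table <- function(tbl) {
  tbl <- tbl[is.finite(tbl$estimated_extent), , drop = FALSE]
  per <- do.call(rbind, lapply(split(tbl, list(tbl$shift, tbl$source),
                                     drop = TRUE), function(d) {
    fit <- fit_extent_regression(d$true_extent, d$estimated_extent)
    data.frame(source = d$source[1], label = d$label[1], shift = d$shift[1],
               slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, n = fit$n)
  }))
  rownames(per) <- NULL
  contrasts <- do.call(rbind, lapply(split(per, per$shift), function(p) {
    fl <- p$slope[p$label == "flat"]; cu <- p$slope[p$label == "curved"]
    t <- if (length(fl) >= 2 && length(cu) >= 2)
      two_sample_t_from_summaries(mean(fl), stats::sd(fl), length(fl),
                                  mean(cu), stats::sd(cu), length(cu))
    else list(t = NA_real_, df = NA_real_, p_value = NA_real_)
    data.frame(shift = p$shift[1],
               mean_slope_flat = if (length(fl)) mean(fl) else NA_real_,
               sd_slope_flat = if (length(fl) >= 2) stats::sd(fl) else NA_real_,
               mean_slope_curved = if (length(cu)) mean(cu) else NA_real_,
               sd_slope_curved = if (length(cu) >= 2) stats::sd(cu) else NA_real_,
               t_flat_vs_curved = t$t, df = t$df,
               n_positive = sum(p$slope > 0), n_sources = nrow(p),
               binomial_p = binomial_one_tailed(sum(p$slope > 0), nrow(p)))
  }))
  rownames(contrasts) <- NULL
  list(per_source = per, contrasts = contrasts)
}
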