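test_that("covariance estimation equals the explicit outer-product sum on a toy", {
  x <- array(0, dim = c(2, 4, 3))
  set.seed(1)
  x[] <- rnorm(length(x))
  w <- beamext:::new_epoch_data(x, 600, 0)
  C <- estimate_covariance(w)
  m <- rbind(x[1, , ], x[2, , ])
  m <- sweep(m, 2, colMeans(m))
  manual <- matrix(0, 3, 3)
  for (i in 1:8) manual <- manual + m[i, ] %o% m[i, ]
  expect_equal(C$matrix, manual / 8, tolerance = 1e-12)
  expect_identical(C$n_samples_used, 8L)
  expect_equal(C$matrix, t(C$matrix))
  expect_true(all(eigen(C$matrix, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-9))
})

test_that("pure white noise gives a near-diagonal covariance and pseudo-Z near 1", {
  ns <- noise_spec()
  w <- simulate_window(rep(0, 30), 0, ns, n_epochs = 60, seed = 2)
  C <- estimate_covariance(w)
  s2 <- white_noise_variance(ns)
  offdiag <- C$matrix[upper.tri(C$matrix)]
  expect_lt(max(abs(offdiag)) / s2, 0.05)
  expect_lt(max(abs(diag(C$matrix) - s2)) / s2, 0.1)
  l <- rnorm(30)
  wt <- beamformer_weights(C, l)
  expect_equal(pseudo_z(wt, C, s2), 1, tolerance = 0.1)
})

test_that("weights are unit-gain, closed-form at identity, and optimal", {
  set.seed(3)
  C <- crossprod(matrix(rnorm(60 * 5), 60, 5)) / 60
  l <- rnorm(5)
  w <- beamformer_weights(C, l)
  expect_equal(sum(w * l), 1, tolerance = 1e-9)

  # C = I closed form
  expect_equal(beamformer_weights(diag(5), l), l / sum(l^2), tolerance = 1e-12)

  # minimum variance among random unit-gain competitors
  vout <- as.numeric(crossprod(w, C %*% w))
  for (k in 1:100) {
    v <- rnorm(5)
    v <- v / sum(v * l)  # unit gain
    expect_gte(as.numeric(crossprod(v, C %*% v)), vout - 1e-12)
  }

  # matches a constrained numeric optimiser on the toy
  obj <- function(th) {  # parameterise unit-gain plane: w0 + null-space coords
    w0 <- l / sum(l^2)
    ns <- svd(matrix(l, 1, 5), nv = 5)$v[, 2:5]
    wv <- w0 + ns %*% th
    as.numeric(crossprod(wv, C %*% wv))
  }
  opt <- optim(rep(0, 4), obj, method = "BFGS")
  expect_equal(vout, opt$value, tolerance = 1e-6)

  # singular covariance errors, pointing at the no-regularisation policy
  Csing <- tcrossprod(matrix(rnorm(10), 5, 2))
  expect_error(beamformer_weights(Csing, l), "regularisation")
})

test_that("pseudo-Z is invariant to weight scaling and monotone in Q", {
  set.seed(4)
  C <- crossprod(matrix(rnorm(200 * 6), 200, 6)) / 200
  w <- rnorm(6)
  expect_equal(pseudo_z(3.7 * w, C, 2), pseudo_z(w, C, 2), tolerance = 1e-12)

  hd <- test_head()
  sa <- test_sensors(60)
  ns <- noise_spec()
  s2 <- white_noise_variance(ns)
  lf <- patch_lead_field(hd, build_disc_patch(c(0, 0, 65), c(1, 0, 0), 6), sa)
  pz <- sapply(c(0, 5, 20), function(Q) {
    w <- simulate_window(lf, Q, ns, n_epochs = 40, seed = 5)
    C <- estimate_covariance(w)
    pseudo_z(beamformer_weights(C, lf$values), C, s2)
  })
  expect_true(all(diff(pz) > 0))
})

test_that("closed-form pseudo-Z equals the weights route", {
  set.seed(6)
  C <- crossprod(matrix(rnorm(300 * 8), 300, 8)) / 300
  l <- rnorm(8)
  w <- beamformer_weights(C, l)
  expect_equal(beamext:::pseudo_z_closed(solve(C), l, 1.3),
               pseudo_z(w, C, 1.3), tolerance = 1e-9)
})

test_that("both orientation solvers recover a point source's orientation", {
  hd <- test_head()
  sa <- test_sensors(96)
  ns <- noise_spec()
  s2 <- white_noise_variance(ns)
  ctr <- c(10, -5, 60)
  true_u <- c(2, 1, 0.5)
  true_u <- true_u / sqrt(sum(true_u^2))
  # only the tangential part of the orientation is magnetically visible in a
  # spherical conductor, so compare against the tangential projection
  radial <- ctr / sqrt(sum(ctr^2))
  u_tan <- true_u - sum(true_u * radial) * radial
  u_tan <- u_tan / sqrt(sum(u_tan^2))
  tang_angle <- function(u) {
    ut <- u - sum(u * radial) * radial
    ut <- ut / sqrt(sum(ut^2))
    acos(min(1, abs(sum(ut * u_tan)))) * 180 / pi
  }
  lf <- patch_lead_field(hd, build_disc_patch(ctr, true_u, 0), sa)
  w <- simulate_window(lf, 50, ns, seed = 7)
  C <- estimate_covariance(w)

  u_sek <- orientation_sekihara(C, disc_basis_lead_fields(hd, ctr, 0, sa))
  expect_lt(tang_angle(u_sek), 5)
  expect_equal(sqrt(sum(u_sek^2)), 1, tolerance = 1e-9)

  u_spin <- orientation_spinning(C, hd, sa, ctr, 0, s2, n_directions = 200)
  expect_lt(tang_angle(u_spin), 5)
  # the two agree (tangentially) at radius 0, where linearity is exact
  expect_lt(abs(tang_angle(u_spin) - tang_angle(u_sek)), 5)

  # u and -u give identical pseudo-Z through the linear basis
  basis <- disc_basis_lead_fields(hd, ctr, 0, sa)
  Ci <- solve(C$matrix)
  expect_equal(beamext:::pseudo_z_closed(Ci, basis %*% u_sek, s2),
               beamext:::pseudo_z_closed(Ci, basis %*% (-u_sek), s2),
               tolerance = 1e-9)
})

test_that("matched disc scans recover the true extent at moderate SNR", {
  hd <- test_head()
  sa <- test_sensors(96)
  ns <- noise_spec()
  s2 <- white_noise_variance(ns)
  ctr <- c(0, 0, 65)
  radii <- seq(0, 20, 2)
  for (true_r in c(6, 10, 14)) {
    lf <- patch_lead_field(hd, build_disc_patch(ctr, c(1, 0, 0), true_r), sa)
    est <- sapply(1:5, function(s) {
      w <- simulate_window(lf, 20, ns, seed = 100 * true_r + s)
      scan_disc_extent(w, hd, sa, ctr, radii, s2)$estimated_extent
    })
    expect_lt(abs(mean(est) - true_r), 2)
  }
})

test_that("small sources are over- rather than under-estimated", {
  hd <- test_head()
  sa <- test_sensors(96)
  ns <- noise_spec()
  s2 <- white_noise_variance(ns)
  ctr <- c(0, 0, 65)
  est <- sapply(1:5, function(s) {
    lf <- patch_lead_field(hd, build_disc_patch(ctr, c(1, 0, 0), 1), sa)
    w <- simulate_window(lf, 10, ns, seed = 600 + s)
    scan_disc_extent(w, hd, sa, ctr, seq(0, 20, 2), s2)$estimated_extent
  })
  expect_gte(mean(est), 1)
})

test_that("a pure-noise window yields a flat low-confidence curve and the smallest radius", {
  hd <- test_head()
  sa <- test_sensors(96)
  ns <- noise_spec()
  s2 <- white_noise_variance(ns)
  ctr <- c(0, 0, 65)
  lf <- patch_lead_field(hd, build_disc_patch(ctr, c(1, 0, 0), 10), sa)
  w0 <- simulate_window(lf, 0, ns, seed = 8)
  res <- scan_disc_extent(w0, hd, sa, ctr, seq(0, 20, 2), s2)
  expect_true(res$flat_curve)
  expect_lt(diff(range(res$pseudo_z)) / max(res$pseudo_z), 0.05)
  # exact ties resolve to the smallest radius
  flat <- beamext:::new_scan_result(c(0, 5, 10), c(2, 2, 2),
                                    matrix(0, 3, 3), NULL)
  expect_identical(flat$estimated_extent, 0)
})

test_that("position optimisation is stationary at a matched optimum and deterministic", {
  hd <- test_head()
  sa <- test_sensors(96)
  ns <- noise_spec()
  s2 <- white_noise_variance(ns)
  ctr <- c(0, 0, 65)
  lf <- patch_lead_field(hd, build_disc_patch(ctr, c(1, 0, 0), 6), sa)
  w <- simulate_window(lf, 50, ns, seed = 9)
  C <- estimate_covariance(w)
  p1 <- optimise_position(C, hd, sa, 6, ctr, s2)
  expect_lt(sqrt(sum((as.vector(p1) - ctr)^2)), 0.5)
  p2 <- optimise_position(C, hd, sa, 6, ctr, s2)
  expect_identical(as.vector(p1), as.vector(p2))
})

test_that("the constrained vertex scan finds the generating vertex on matched data", {
  mesh <- local_cortex(40)
  hd <- test_head()
  sa <- test_sensors(96)
  ns <- noise_spec()
  s2 <- white_noise_variance(ns)
  tv <- pick_target_vertices(mesh, 3, seed = 4)[2]
  truth <- build_cortical_patch(mesh, tv, 8)
  lf <- patch_lead_field(hd, truth, sa)
  w <- simulate_window(lf, 50, ns, seed = 10)
  C <- estimate_covariance(w)
  pre <- precompute_cortical_scan(mesh, tv, hd, sa, max_distance = 12,
                                  max_radius = 12)
  sc <- constrained_vertex_scan(pre, C, 8, s2)
  expect_lt(sqrt(sum((sc$centre - mesh$vertices[tv, ])^2)), 2)
  # no candidate farther than the constraint is ever considered
  expect_true(all(pre$cand_euclid <= 12 + 1e-9))
  # full scan estimates the true extent
  res <- scan_cortical_extent(w, pre, seq(0, 16, 2), s2,
                              truth_centre = mesh$vertices[tv, ])
  expect_lt(abs(res$estimated_extent - 8), 2.1)
})

test_that("the fast cortical scan equals the explicit weights route", {
  mesh <- local_cortex(40)
  hd <- test_head()
  sa <- test_sensors(60)
  ns <- noise_spec()
  s2 <- white_noise_variance(ns)
  tv <- pick_target_vertices(mesh, 3, seed = 4)[1]
  truth <- build_cortical_patch(mesh, tv, 6)
  lf <- patch_lead_field(hd, truth, sa)
  w <- simulate_window(lf, 20, ns, n_epochs = 40, seed = 11)
  C <- estimate_covariance(w)
  pre <- precompute_cortical_scan(mesh, tv, hd, sa, max_distance = 0,
                                  max_radius = 10)
  sc <- constrained_vertex_scan(pre, C, 6, s2)
  # independent route: explicit patch lead field + weights + pseudo-Z
  model <- build_cortical_patch(mesh, tv, 6)
  lfm <- patch_lead_field(hd, model, sa)
  wts <- beamformer_weights(C, lfm)
  expect_equal(sc$pseudo_z, pseudo_z(wts, C, s2), tolerance = 1e-6)
})

test_that("Sekihara's solver under-estimates large extents at high SNR where spinning does not", {
  hd <- test_head()
  # the linearisation bias needs the full desk-scale array to be resolved
  sa <- test_sensors(120)
  ns <- noise_spec()
  s2 <- white_noise_variance(ns)
  ctr <- c(0, 0, 65)
  ori <- c(1, 1, 0.25); ori <- ori / sqrt(sum(ori^2))
  lf <- patch_lead_field(hd, build_disc_patch(ctr, ori, 18), sa)
  radii <- seq(0, 20, 2)
  est <- sapply(21:23, function(s) {
    w <- simulate_window(lf, 100, ns, seed = s)
    c(sek = scan_disc_extent(w, hd, sa, ctr, radii, s2,
                             orientation = "sekihara")$estimated_extent,
      spin = scan_disc_extent(w, hd, sa, ctr, radii, s2,
                              orientation = "spinning",
                              n_directions = 60)$estimated_extent)
  })
  expect_lt(abs(mean(est["spin", ]) - 18), 2.1)
  expect_lt(mean(est["sek", ]), mean(est["spin", ]))
})
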