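test_that("disc patches have the expected element count and geometry", {
  # radius 0: the pure dipole case
  p0 <- build_disc_patch(c(0, 0, 65), c(1, 0, 0), 0)
  expect_identical(nrow(p0$positions), 1L)
  expect_equal(p0$positions[1, ], c(0, 0, 65))

  # grid points in a circle: count close to pi r^2 / spacing^2
  p10 <- build_disc_patch(c(0, 0, 65), c(0, 0, 1), 10, spacing = 1)
  expect_lt(abs(nrow(p10$positions) - pi * 100) / (pi * 100), 0.03)

  # all orientations equal the supplied normal; elements coplanar
  n <- c(1, 2, 2) / 3
  p <- build_disc_patch(c(5, -3, 60), n, 7)
  expect_true(all(abs(sweep(p$orientations, 2, n)) < 1e-12))
  offs <- sweep(p$positions, 2, c(5, -3, 60))
  expect_lt(max(abs(offs %*% n)), 1e-9)
  expect_true(all(sqrt(rowSums(offs^2)) <= 7 + 1e-9))
})

test_that("disc element count is invariant under rotation of the normal", {
  set.seed(1)
  counts <- replicate(10, {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    nrow(build_disc_patch(c(0, 0, 0), u, 9.5)$positions)
  })
  expect_identical(length(unique(counts)), 1L)
})

test_that("cortical patches grow by geodesic distance and nest", {
  mesh <- local_cortex(40)
  tv <- 800L
  d <- geodesic_distances(mesh, tv)
  p0 <- build_cortical_patch(mesh, tv, 0, distances = d)
  expect_identical(nrow(p0$positions), 1L)
  expect_equal(p0$positions[1, ], mesh$vertices[tv, ])

  prev <- NULL
  for (r in c(2, 5, 8, 12)) {
    p <- build_cortical_patch(mesh, tv, r, distances = d)
    keys <- apply(p$positions, 1, paste, collapse = ",")
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
  expect_error(build_cortical_patch(mesh, nrow(mesh$vertices) + 1L, 5),
               "out of range")
})

test_that("on a flat sheet the geodesic patch equals Euclidean selection", {
  mesh <- make_synthetic_cortex(25, fold_amplitude = 0, cap_radius = Inf,
                                target_spacing = 1, seed = 9)
  ctr <- which.min(rowSums(sweep(mesh$vertices, 2, colMeans(mesh$vertices))^2))
  p <- build_cortical_patch(mesh, ctr, 8)
  eu <- sqrt(rowSums(sweep(mesh$vertices, 2, mesh$vertices[ctr, ])^2))
  eucl_set <- which(eu <= 8)
  # graph distance exceeds Euclidean by the lattice metric inflation (up to
  # ~20% on a jittered triangular grid), so the patch is a subset of the
  # Euclidean ball and must cover the proportionally shrunken ball
  keys_patch <- apply(p$positions, 1, paste, collapse = ",")
  keys_inner <- apply(mesh$vertices[eu <= 8 / 1.25, , drop = FALSE], 1, paste,
                      collapse = ",")
  expect_true(all(keys_patch %in%
                  apply(mesh$vertices[eucl_set, , drop = FALSE], 1, paste,
                        collapse = ",")))
  expect_true(all(keys_inner %in% keys_patch))
})

test_that("moment assignment conserves totals in both modes", {
  p <- build_disc_patch(c(0, 0, 65), c(1, 0, 0), 10)
  n <- nrow(p$positions)

  pq <- assign_moments(p, "total_moment", Q = 20)
  expect_equal(sum(pq$moments), 20, tolerance = 1e-9)
  expect_equal(pq$moments, rep(20 / n, n))
  expect_equal(mean(pq$moments), 0.0637, tolerance = 0.02)

  p0 <- assign_moments(p, "total_moment", Q = 0)
  expect_true(all(p0$moments == 0))

  # constant current density: 50 pAm/mm^2 over ~100 mm^2 -> ~5 nAm total;
  # construct exactly 100 mm^2 with a synthetic area
  pa <- p
  pa$element_area <- rep(100 / n, n)
  pccd <- assign_moments(pa, "constant_current_density", ccd = 50)
  expect_equal(sum(pccd$moments), 5, tolerance = 1e-12)

  # moment conservation across radii and kinds
  mesh <- local_cortex(40)
  for (r in c(0, 4, 9)) {
    pc <- build_cortical_patch(mesh, 700L, r, total_moment = 3)
    expect_equal(sum(pc$moments), 3, tolerance = 1e-9)
  }
})

test_that("patch curvature matches symmetry cases and the spherical-cap form", {
  # identical normals -> 0
  p <- patch_source(matrix(0, 3, 3), matrix(rep(c(0, 0, 1), 3), 3, byrow = TRUE),
                    rep(1, 3), c(0, 0, 0), 1, "disc")
  expect_equal(patch_curvature(p), 0, tolerance = 1e-12)

  # two orthogonal normals -> 45 degrees each side of the bisector
  p2 <- patch_source(matrix(0, 2, 3), rbind(c(1, 0, 0), c(0, 1, 0)),
                     c(1, 1), c(0, 0, 0), 1, "disc")
  expect_equal(patch_curvature(p2), 45, tolerance = 1e-9)

  # opposing normals -> degenerate mean, flagged maximally curved
  p3 <- patch_source(matrix(0, 2, 3), rbind(c(0, 0, 1), c(0, 0, -1)),
                     c(1, 1), c(0, 0, 0), 1, "disc")
  expect_equal(patch_curvature(p3), 90)

  # spherical cap of half-angle theta, uniform by area:
  # mean angle to the axis = (sin t - t cos t) / (1 - cos t)
  set.seed(3)
  theta <- 30 * pi / 180
  z <- runif(4000, cos(theta), 1)   # area-uniform on the cap
  phi <- runif(4000, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  normals <- cbind(r * cos(phi), r * sin(phi), z)
  pc <- patch_source(normals * 50, normals, rep(1, 4000), c(0, 0, 0), 10,
                     "cortical")
  closed_form <- (sin(theta) - theta * cos(theta)) / (1 - cos(theta)) * 180 / pi
  expect_equal(patch_curvature(pc), closed_form, tolerance = 0.02)
})

test_that("median-split classification halves even groups and honours ties", {
  set.seed(8)
  curv <- runif(20, 2, 25)
  lab <- classify_curvature(curv)
  expect_identical(sum(lab == "curved"), 10L)
  expect_identical(sum(lab == "flat"), 10L)
  # order invariance
  perm <- sample(20)
  expect_identical(classify_curvature(curv[perm]), lab[perm])
  # all-equal: everything flat by the tie rule
  expect_true(all(classify_curvature(rep(5, 6)) == "flat"))
})
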