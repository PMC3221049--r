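#' Triangulated cortical sheet
#'
#' A `trimesh` is a list with `vertices` (n x 3 matrix, mm, head frame),
#' `triangles` (m x 3 integer matrix of 1-based vertex indices) and `normals`
#' (n x 3 matrix of per-vertex unit outward normals). The head frame has its
#' origin at the centre of the spherical volume conductor and +z pointing
#' towards the sensor helmet.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param triangles integer m x 3 matrix of vertex indices (1-based).
#' @param normals optional n x 3 matrix of unit normals; computed with
#'   [vertex_normals()] when omitted.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, triangles, normals = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices must lie in 1..nrow(vertices)")
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         normals = NULL), class = "trimesh")
  mesh$normals <- if (is.null(normals)) vertex_normals(mesh) else as.matrix(normals)
  mesh
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d triangles, mean edge %.2f mm\n",
              nrow(x$vertices), nrow(x$triangles), mean(edge_lengths(x))))
  invisible(x)
}

row_norms <- function(m) sqrt(rowSums(m * m))

unit_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

#' Unique edges of a mesh
#'
#' @param mesh a [trimesh()].
#' @return Integer e x 2 matrix of unique vertex index pairs.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Edge lengths of a mesh (mm)
#'
#' @param mesh a [trimesh()].
#' @return Numeric vector of Euclidean edge lengths.
#' @export
edge_lengths <- function(mesh) {
  e <- mesh_edges(mesh)
  row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
            mesh$vertices[e[, 2], , drop = FALSE])
}

#' Area-weighted per-vertex normals
#'
#' Each vertex normal is the area-weighted mean of the normals of its incident
#' triangles, renormalised to unit length. Triangle winding is taken as given;
#' the sheet is then oriented consistently so that the mean normal points
#' towards +z (the helmet side).
#'
#' @param mesh a [trimesh()] (its stored `normals`, if any, are ignored).
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  # cross product rows; magnitude = 2 * triangle area, so summing these is
  # exactly area weighting
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + tabulate_weighted(tr[, k], cr[, 1], nrow(v))
    n[, 2] <- n[, 2] + tabulate_weighted(tr[, k], cr[, 2], nrow(v))
    n[, 3] <- n[, 3] + tabulate_weighted(tr[, k], cr[, 3], nrow(v))
  }
  lens <- row_norms(n)
  if (any(lens < 1e-12))
    stop("mesh has isolated or degenerate vertices (no incident triangle area)")
  n <- n / lens
  if (mean(n[, 3]) < 0) n <- -n
  n
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Barycentric vertex areas (mm^2)
#'
#' One third of the summed area of the triangles incident to each vertex; the
#' standard mesh area lumping used to convert a current density into element
#' moments on a cortical patch.
#'
#' @param mesh a [trimesh()].
#' @return Numeric vector of per-vertex areas.
#' @export
vertex_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  tri_area <- 0.5 * row_norms(cr)
  out <- numeric(nrow(v))
  for (k in 1:3) out <- out + tabulate_weighted(tr[, k], tri_area / 3, nrow(v))
  out
}

mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
                 mesh$vertices[e[, 2], , drop = FALSE])
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Geodesic (cortical) distances along mesh edges
#'
#' Shortest-path distance along the edge graph of the mesh, with each edge
#' weighted by its Euclidean length. This is the "cortical distance" used to
#' grow surface-following patches; it is always at least the straight-line
#' distance. Vertices in a disconnected component are reported as `Inf`.
#'
#' @param mesh a [trimesh()].
#' @param seed_vertex integer vertex index (1-based), or a vector of indices.
#' @return If `seed_vertex` is scalar, a numeric vector of distances (mm) to
#'   every vertex; otherwise a matrix with one row per seed.
#' @export
geodesic_distances <- function(mesh, seed_vertex) {
  seed_vertex <- as.integer(seed_vertex)
  if (any(seed_vertex < 1L) || any(seed_vertex > nrow(mesh$vertices)))
    stop("seed_vertex out of range")
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = seed_vertex, algorithm = "dijkstra")
  if (length(seed_vertex) == 1L) drop(d) else d
}

#' Rigid shift emulating a co-registration error
#'
#' Translates every vertex by `magnitude` mm along a uniformly random unit
#' direction drawn from `direction_seed`. Topology and normals are unchanged:
#' this is exactly what a rigid mis-registration of the anatomical surface in
#' the sensor frame does. The shifted surface is intended to be used as the
#' beamformer's model surface while the data are generated from the original.
#'
#' @param mesh a [trimesh()].
#' @param magnitude shift length in mm (>= 0).
#' @param direction_seed integer seed selecting the random direction.
#' @return The shifted `trimesh`, with attribute `"shift_vector"`.
#' @export
shift_mesh <- function(mesh, magnitude, direction_seed = 1L) {
  stopifnot(magnitude >= 0)
  u <- local({
    set.seed(as.integer(direction_seed))
    repeat {
      v <- stats::rnorm(3)
      if (sqrt(sum(v^2)) > 1e-12) break
    }
    v / sqrt(sum(v^2))
  })
  out <- mesh
  out$vertices <- mesh$vertices + rep(magnitude * u, each = nrow(mesh$vertices))
  attr(out, "shift_vector") <- magnitude * u
  out
}

#' Synthetic folded cortical sheet
#'
#' Generates a connected triangulated sheet emulating a patch of pial surface:
#' a triangular lattice folded by a product-sinusoid height field and bent
#' onto a spherical cap so that the sheet sits below a sensor helmet. The
#' product sinusoid gives regions of high curvature (antinodes, gyral/sulcal
#' crowns) and low curvature (nodal lines), the two regimes the extent
#' estimator behaves differently in. Vertex positions receive a small seeded
#' in-plane jitter so the lattice is not pathologically symmetric. The
#' in-plane spacing is rescaled once so that the mean edge length after
#' folding matches `target_spacing`.
#'
#' @param extent_mm side length of the sheet (mm).
#' @param fold_amplitude peak fold height (mm); 0 gives an unfolded cap.
#' @param fold_wavelength fold wavelength (mm).
#' @param target_spacing requested mean inter-vertex (edge) distance (mm).
#' @param seed integer seed for the jitter.
#' @param cap_radius bending radius of the spherical cap (mm); `Inf` gives a
#'   flat sheet.
#' @param centre 3-vector: position of the sheet centre in the head frame (mm).
#' @return A [trimesh()].
#' @export
make_synthetic_cortex <- function(extent_mm, fold_amplitude = 3,
                                  fold_wavelength = 25, target_spacing = 1,
                                  seed = 1L, cap_radius = 200,
                                  centre = c(0, 0, 65)) {
  if (extent_mm <= 0 || target_spacing <= 0 || fold_wavelength <= 0)
    stop("extent_mm, target_spacing and fold_wavelength must be positive")
  if (fold_amplitude < 0) stop("fold_amplitude must be >= 0")

  build <- function(spacing) {
    nu <- max(2L, as.integer(round(extent_mm / spacing)) + 1L)
    dv <- spacing * sqrt(3) / 2
    nv <- max(2L, as.integer(round(extent_mm / dv)) + 1L)
    u0 <- (seq_len(nu) - (nu + 1) / 2) * spacing
    v0 <- (seq_len(nv) - (nv + 1) / 2) * dv
    u <- outer(u0, rep(1, nv)) + outer(rep(spacing / 2, nu), (seq_len(nv) %% 2))
    v <- outer(rep(1, nu), v0)
    set.seed(as.integer(seed))
    jit <- 0.08 * spacing
    u <- u + matrix(stats::runif(nu * nv, -jit, jit), nu, nv)
    v <- v + matrix(stats::runif(nu * nv, -jit, jit), nu, nv)
    # fold amplitude ramps across the sheet: one end stays smooth (low
    # curvature, like a gyral crown), the other is fully folded, so a single
    # sheet contains both curvature regimes
    env <- pmin(1, pmax(0, u / extent_mm + 0.5))
    z <- fold_amplitude * env * sin(2 * pi * u / fold_wavelength) *
      sin(2 * pi * v / fold_wavelength)
    idx <- matrix(seq_len(nu * nv), nu, nv)
    tris <- vector("list", nv - 1L)
    for (j in seq_len(nv - 1L)) {
      i <- seq_len(nu - 1L)
      if (j %% 2 == 0L) {
        t1 <- cbind(idx[i, j], idx[i + 1, j], idx[i, j + 1])
        t2 <- cbind(idx[i + 1, j], idx[i + 1, j + 1], idx[i, j + 1])
      } else {
        t1 <- cbind(idx[i, j], idx[i + 1, j], idx[i + 1, j + 1])
        t2 <- cbind(idx[i, j], idx[i + 1, j + 1], idx[i, j + 1])
      }
      tris[[j]] <- rbind(t1, t2)
    }
    uv <- cbind(as.vector(u), as.vector(v), as.vector(z))
    verts <- bend_onto_cap(uv, cap_radius, centre)
    trimesh(verts, do.call(rbind, tris))
  }

  mesh <- build(target_spacing)
  m <- mean(edge_lengths(mesh))
  if (abs(m - target_spacing) / target_spacing > 0.02)
    mesh <- build(target_spacing^2 / m)
  mesh
}

bend_onto_cap <- function(uvz, cap_radius, centre) {
  if (!is.finite(cap_radius))
    return(cbind(uvz[, 1] + centre[1], uvz[, 2] + centre[2],
                 uvz[, 3] + centre[3]))
  rho <- sqrt(uvz[, 1]^2 + uvz[, 2]^2)
  theta <- rho / cap_radius
  s <- ifelse(rho > 1e-12, sin(theta) / rho, 1 / cap_radius)
  dir <- cbind(uvz[, 1] * s, uvz[, 2] * s, cos(theta))
  cb <- centre - c(0, 0, cap_radius)
  (cap_radius + uvz[, 3]) * dir + rep(cb, each = nrow(uvz))
}

#' Write / read a mesh as Wavefront OBJ
#'
#' Minimal OBJ support (`v` and `f` records, positions in mm) for exchanging
#' surfaces with external tools.
#'
#' @param mesh a [trimesh()].
#' @param path file path.
#' @return `write_mesh_obj` returns `path` invisibly; `read_mesh_obj` returns
#'   a [trimesh()].
#' @export
write_mesh_obj <- function(mesh, path) {
  v <- sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2],
               mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$triangles[, 1], mesh$triangles[, 2],
               mesh$triangles[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
read_mesh_obj <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  verts <- do.call(rbind, lapply(strsplit(vs, "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  tris <- do.call(rbind, lapply(strsplit(fs, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  trimesh(verts, tris)
}
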