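# Fixture meshes, scenes and independent oracles, all built in code.

# axis-aligned box mesh
box_mesh <- function(lo = c(0, 0, 0), hi = c(10, 10, 10), label = NULL) {
  lo <- rep(lo, length.out = 3); hi <- rep(hi, length.out = 3)
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  f <- rbind(c(1, 3, 2), c(2, 3, 4),    # z = lo
             c(5, 6, 7), c(6, 8, 7),    # z = hi
             c(1, 2, 5), c(2, 6, 5),    # y = lo
             c(3, 7, 4), c(4, 7, 8),    # y = hi
             c(1, 5, 3), c(3, 5, 7),    # x = lo
             c(2, 4, 6), c(4, 8, 6))    # x = hi
  surface_mesh(v, f, label = label)
}

# capped cylinder along z, centered at origin
cylinder_mesh <- function(radius = 25, length = 100, n_theta = 32,
                          n_z = 9, label = NULL) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  z <- seq(-length / 2, length / 2, length.out = n_z)
  verts <- do.call(rbind, lapply(z, function(zz)
    cbind(radius * cos(theta), radius * sin(theta), zz)))
  verts <- rbind(verts, c(0, 0, -length / 2), c(0, 0, length / 2))
  i_bot <- nrow(verts) - 1L; i_top <- nrow(verts)
  idx <- function(i, j) (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  faces <- list()
  for (j in seq_len(n_z - 1)) {
    i <- seq_len(n_theta)
    a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i, j + 1); d <- idx(i + 1, j + 1)
    faces[[j]] <- rbind(cbind(a, b, d), cbind(a, d, cc))
  }
  i <- seq_len(n_theta)
  faces[[n_z]] <- cbind(i_bot, idx(i + 1, 1), idx(i, 1))
  faces[[n_z + 1]] <- cbind(i_top, idx(i, n_z), idx(i + 1, n_z))
  surface_mesh(verts, do.call(rbind, faces), label = label)
}

# memoised fixture scenes (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name) {
  got <- .fixture_env[[name]]
  if (!is.null(got)) return(got)
  val <- switch(name,
    # small centered sphere tumor in a shaft: ~8k healthy voxels
    small_scene = make_scene(
      phantom_spec(shaft_radius = 16, shaft_length = 90, tumor_radii = 9,
                   tumor_center = c(0, 0, 10)), pitch = 2),
    # tiny scene for brute-force oracles (~2.5k healthy voxels)
    tiny_scene = make_scene(
      phantom_spec(shaft_radius = 12, shaft_length = 60, condyle_bulge = 0.2,
                   tumor_radii = 7, tumor_center = c(0, 0, 8),
                   mesh_resolution = 1), pitch = 2),
    # eccentric lobed tumor breaching the cortex (extraosseous extension)
    eccentric_scene = make_scene(
      phantom_spec(shaft_radius = 16, shaft_length = 90,
                   tumor_shape = "lobed", tumor_radii = 9,
                   tumor_center = c(10, 4, 5), lobe_amplitude = 0.15,
                   seed = 7), pitch = 2),
    stop("unknown fixture ", name))
  .fixture_env[[name]] <- val
  val
}

# LP oracle: is p a convex combination of the generator rows?
lp_in_hull <- function(points, generators, tol = 1e-7) {
  g <- t(generators)                       # d x m
  m <- ncol(g)
  Aeq <- rbind(g, rep(1, m))
  apply(rbind(points), 1, function(p) {
    sol <- tryCatch(
      suppressWarnings(pracma::linprog(cc = rep(0, m), Aeq = Aeq,
                                       beq = c(p, 1), maxiter = 200)),
      error = function(e) NULL)
    !is.null(sol) && !is.null(sol$x) && !anyNA(sol$x) &&
      max(abs(Aeq %*% sol$x - c(p, 1))) < tol && min(sol$x) > -tol
  })
}

# LP oracle: is p a *conic* combination of the generator rows (apex at 0)?
lp_in_cone <- function(points, generators, tol = 1e-7) {
  g <- t(generators)
  m <- ncol(g)
  apply(rbind(points), 1, function(p) {
    sol <- tryCatch(
      suppressWarnings(pracma::linprog(cc = rep(0, m), Aeq = g, beq = p,
                                       maxiter = 200)),
      error = function(e) NULL)
    !is.null(sol) && !is.null(sol$x) && !anyNA(sol$x) &&
      max(abs(g %*% sol$x - p)) < tol * max(1, max(abs(p))) &&
      min(sol$x) > -tol
  })
}

# generalized winding number: inside iff total solid angle ~ +-4*pi
winding_inside <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  points <- rbind(points)
  omega <- numeric(nrow(points))
  for (t in seq_len(nrow(f))) {
    a <- sweep(points, 2, v[f[t, 1], ], `-`) * -1
    b <- sweep(points, 2, v[f[t, 2], ], `-`) * -1
    cc <- sweep(points, 2, v[f[t, 3], ], `-`) * -1
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(cc^2))
    det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
            a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
            a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(b * cc) * la +
      rowSums(a * cc) * lb
    omega <- omega + 2 * atan2(det3, den)
  }
  abs(omega) > 2 * pi
}

# brute-force removed set: per-voxel geometric test with no hull facets —
# conic-combination LP against the local tumor hull vertices, plus the
# facing cut (flat) / 2D convex-combination LP on the xz projection
# (contoured). Only usable on small scenes.
brute_force_removed <- function(sc, params) {
  loc <- to_local(sc, params)
  hull_pts <- loc$tumor_vertices[
    convex_hull_3d(loc$tumor_vertices)$vertices, , drop = FALSE]
  B <- loc$healthy_bone
  cand <- which(B[, 3] >= -1e-9)
  inside <- lp_in_cone(B[cand, , drop = FALSE], hull_pts)
  removed <- cand[inside]
  zmin <- min(loc$tumor_vertices[, 3])
  if (params$rg_type == "flat") {
    removed <- removed[B[removed, 3] > zmin - 1e-9]
  }
  if (params$rg_type == "contoured") {
    in2d <- lp_in_hull(B[removed, c(1, 3), drop = FALSE],
                       cbind(hull_pts[, 1], hull_pts[, 3]))
    removed <- removed[in2d]
  }
  sort(removed)
}

# random in-bounds parameter draws for a scene (static box, then the
# package clamps exactly as the optimizer does)
random_params <- function(sc, rg_type, n, seed) {
  b <- bounds_for(rg_type, sc)
  set.seed(seed)
  X <- sapply(seq_along(b$lower), function(j)
    stats::runif(n, b$lower[j], b$upper[j]))
  lapply(seq_len(n), function(i) resectplanr:::vector_params(X[i, ], rg_type))
}
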