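#' Elementary rotation matrices
#'
#' Right-handed rotation matrices about the fixed coordinate axes, in degrees.
#' Resection parameters are applied as extrinsic rotations about the base
#' z-, then y-, then x-axis (see [rg_rotation()]).
#'
#' @param deg rotation angle in degrees.
#' @return A 3x3 orthonormal rotation matrix.
#' @keywords internal
#' @name rotations
NULL

#' @rdname rotations
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

#' @rdname rotations
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c( cos(a), 0, sin(a),
            0,      1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rotations
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0,       0,
           0, cos(a), -sin(a),
           0, sin(a),  cos(a)), 3, 3, byrow = TRUE)
}

#' Composite resection-frame rotation
#'
#' Extrinsic z-y-x rotation used to realign the scene before the local
#' translation is applied: a point `p` maps to `R %*% p` with
#' `R = Rx(theta_x) Ry(theta_y) Rz(theta_z)` (the z rotation acts first).
#'
#' @param theta_z,theta_y,theta_x rotations about the base axes, degrees.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @export
rg_rotation <- function(theta_z, theta_y, theta_x) {
  R <- rot_x(theta_x) %*% rot_y(theta_y) %*% rot_z(theta_z)
  stopifnot(abs(det(R) - 1) < 1e-12)
  R
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product of n x 3 matrices
rowwise_cross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

#' Icosphere mesh
#'
#' Triangulated unit sphere obtained by recursive subdivision of an
#' icosahedron, with vertices projected back to the sphere after each
#' subdivision. Used as the angular scaffold of tumor phantoms and as a
#' convenient watertight test solid.
#'
#' @param subdivisions non-negative integer; 0 gives the icosahedron
#'   (12 vertices, 20 faces); each level quadruples the face count.
#' @param radius sphere radius (mm).
#' @param center length-3 numeric center (mm).
#' @return A [surface_mesh()].
#' @examples
#' m <- icosphere(2)
#' nrow(m$faces)  # 320
#' @export
icosphere <- function(subdivisions = 2, radius = 1, center = c(0, 0, 0)) {
  stopifnot(subdivisions >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1,  phi, 0,   1,  phi, 0,  -1, -phi, 0,   1, -phi, 0,
                 0, -1,  phi,  0,  1,  phi,  0, -1, -phi,  0,  1, -phi,
                 phi, 0, -1,   phi, 0,  1,  -phi, 0, -1,  -phi, 0,  1),
              ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(1,12,6, 1,6,2, 1,2,8, 1,8,11, 1,11,12,
                2,6,10, 6,12,5, 12,11,3, 11,8,7, 8,2,9,
                4,10,5, 4,5,3, 4,3,7, 4,7,9, 4,9,10,
                5,10,6, 3,5,12, 7,3,11, 9,7,8, 10,9,2),
              ncol = 3, byrow = TRUE)
  for (s in seq_len(subdivisions)) {
    edge_key <- new.env(parent = emptyenv())
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edge_key[[key]]
      if (!is.null(idx)) return(idx)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      edge_key[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4 * k - 3):(4 * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  v <- sweep(v * radius, 2, center, `+`)
  surface_mesh(v, f)
}

#' Star-shaped radial mesh
#'
#' Meshes the surface `c + r(u) * u` over unit directions `u` taken from an
#' icosphere, where `r` is a strictly positive radial function. Every such
#' surface is star-shaped about `c`, which guarantees that uniform margin
#' expansion about the centroid contains the original solid.
#'
#' @param radial_fn function taking an n x 3 matrix of unit directions and
#'   returning n positive radii (mm).
#' @param center length-3 numeric center (mm).
#' @param subdivisions icosphere subdivision level.
#' @return A [surface_mesh()].
#' @export
radial_mesh <- function(radial_fn, center = c(0, 0, 0), subdivisions = 2) {
  ico <- icosphere(subdivisions)
  u <- ico$vertices
  r <- radial_fn(u)
  stopifnot(all(is.finite(r)), all(r > 0))
  surface_mesh(sweep(u * r, 2, center, `+`), ico$faces)
}

#' Unit direction grid on the sphere
#'
#' Deduplicated icosphere vertex directions; used for the planar-baseline
#' grid search over cut-plane normals.
#'
#' @param subdivisions icosphere subdivision level.
#' @return n x 3 matrix of unit vectors (antipodal pairs removed).
#' @keywords internal
sphere_directions <- function(subdivisions = 1) {
  u <- icosphere(subdivisions)$vertices
  # keep one of each antipodal pair: positive z, break ties on y then x
  keep <- u[, 3] > 1e-9 |
    (abs(u[, 3]) <= 1e-9 & (u[, 2] > 1e-9 | (abs(u[, 2]) <= 1e-9 & u[, 1] > 0)))
  rbind(u[keep, , drop = FALSE], -u[keep, , drop = FALSE])
}
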