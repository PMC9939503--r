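#' 3D convex hull
#'
#' Incremental convex hull of a 3D point set. Faces are consistently
#' oriented with outward unit normals; each facet defines the half-space
#' `n . x <= d`. Points within `tol` of the current hull surface are
#' treated as interior during construction.
#'
#' @param points n x 3 numeric matrix, n >= 4, not all coplanar.
#' @param tol construction tolerance (mm); default scales with the data.
#' @return An object of class `hull3d`: list with `points` (the input),
#'   `vertices` (indices of hull vertices), `faces` (f x 3 index triples
#'   into `points`), `normals` (f x 3 outward unit normals), `offsets`
#'   (length f, `d` in `n . x <= d`), and `interior` (a strictly interior
#'   point).
#' @export
convex_hull_3d <- function(points, tol = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 4) stop("degenerate hull: need at least 4 points")
  scale <- max(abs(sweep(points, 2, colMeans(points))), 1)
  if (is.null(tol)) tol <- 1e-10 * scale

  # --- initial tetrahedron from extreme points
  i1 <- which.min(points[, 1]); i2 <- which.max(points[, 1])
  if (max(abs(points[i2, ] - points[i1, ])) < tol) {
    # all x equal; fall back to other axes
    i1 <- which.min(points[, 2]); i2 <- which.max(points[, 2])
  }
  d12 <- points[i2, ] - points[i1, ]
  if (sqrt(sum(d12^2)) < tol) stop("degenerate hull: points coincide")
  rel <- sweep(points, 2, points[i1, ])
  t_param <- (rel %*% d12) / sum(d12^2)
  perp <- rel - outer(as.vector(t_param), d12)
  i3 <- which.max(rowSums(perp^2))
  if (sqrt(sum(perp[i3, ]^2)) < tol) stop("degenerate hull: points are collinear")
  n0 <- vec_cross(points[i2, ] - points[i1, ], points[i3, ] - points[i1, ])
  n0 <- n0 / sqrt(sum(n0^2))
  h <- rel %*% n0
  i4 <- which.max(abs(h))
  if (abs(h[i4]) < tol) stop("degenerate hull: points are coplanar")
  interior <- colMeans(points[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  geo <- facet_planes(points, faces, interior)
  faces <- geo$faces; normals <- geo$normals; offsets <- geo$offsets

  # --- insert remaining points, farthest-outside first
  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  if (length(remaining)) {
    # process in decreasing distance from the interior point: tends to keep
    # intermediate hulls fat and the facet count low
    dists <- rowSums(sweep(points[remaining, , drop = FALSE], 2, interior)^2)
    remaining <- remaining[order(-dists)]
  }
  for (i in remaining) {
    d <- as.vector(normals %*% points[i, ]) - offsets
    vis <- d > tol
    if (!any(vis)) next
    hz <- horizon_edges(faces, vis)
    if (nrow(hz) == 0) next   # numerically interior after all
    new_faces <- cbind(hz, i)
    faces <- rbind(faces[!vis, , drop = FALSE], new_faces)
    geo <- facet_planes(points, faces, interior)
    faces <- geo$faces; normals <- geo$normals; offsets <- geo$offsets
  }
  structure(list(points = points,
                 vertices = sort(unique(as.vector(faces))),
                 faces = faces, normals = normals, offsets = offsets,
                 interior = interior),
            class = "hull3d")
}

# outward-oriented facet planes; flips face windings that face the interior
facet_planes <- function(points, faces, interior) {
  a <- points[faces[, 1], , drop = FALSE]
  nrm <- rowwise_cross(points[faces[, 2], , drop = FALSE] - a,
                       points[faces[, 3], , drop = FALSE] - a)
  len <- sqrt(rowSums(nrm^2))
  keep <- len > .Machine$double.eps
  faces <- faces[keep, , drop = FALSE]
  nrm <- nrm[keep, , drop = FALSE] / len[keep]
  a <- a[keep, , drop = FALSE]
  offs <- rowSums(nrm * a)
  flip <- as.vector(nrm %*% interior) > offs
  if (any(flip)) {
    faces[flip, ] <- faces[flip, c(1, 3, 2), drop = FALSE]
    nrm[flip, ] <- -nrm[flip, , drop = FALSE]
    offs[flip] <- -offs[flip]
  }
  list(faces = faces, normals = nrm, offsets = offs)
}

# directed edges of visible faces whose twin lies in a non-visible face
horizon_edges <- function(faces, visible) {
  vf <- faces[visible, , drop = FALSE]
  nf <- faces[!visible, , drop = FALSE]
  ve <- rbind(vf[, 1:2], vf[, 2:3], vf[, c(3, 1)])
  ne <- rbind(nf[, 1:2], nf[, 2:3], nf[, c(3, 1)])
  keep <- paste(ve[, 2], ve[, 1]) %in% paste(ne[, 1], ne[, 2])
  ve[keep, , drop = FALSE]
}

#' Point membership in a 3D convex hull
#'
#' Tests whether points lie inside (or within `tol` of) the convex hull of
#' a generator set, via the hull's facet half-space inequalities. Boundary
#' points count as inside.
#'
#' @param points q x 3 matrix of query points.
#' @param hull_generators g x 3 matrix (g >= 4, affinely independent), or a
#'   prebuilt `hull3d`.
#' @param tol membership tolerance (mm), default 1e-9.
#' @return Logical vector of length q.
#' @export
point_in_hull_3d <- function(points, hull_generators, tol = 1e-9) {
  hull <- if (inherits(hull_generators, "hull3d")) hull_generators
          else convex_hull_3d(hull_generators)
  points <- rbind(points)
  d <- points %*% t(hull$normals)
  d <- sweep(d, 2, hull$offsets)
  apply(d, 1, max) <= tol
}

# Half-space mask on many points (hot path). Facets are visited in small
# blocks and points already outside are dropped from later blocks; a fixed
# pseudo-random facet order makes the early blocks directionally diverse so
# most exterior points are eliminated immediately.
hull_mask <- function(points, normals, offsets, tol = 1e-9, block = 8L) {
  n <- nrow(points)
  if (n == 0) return(logical(0))
  nf <- nrow(normals)
  ord <- facet_order(nf)
  active <- seq_len(n)
  j <- 1L
  while (j <= nf && length(active)) {
    jj <- ord[j:min(j + block - 1L, nf)]
    d <- points[active, , drop = FALSE] %*% t(normals[jj, , drop = FALSE])
    ok <- d[, 1] <= offsets[jj[1]] + tol
    for (k in seq_along(jj)[-1]) ok <- ok & (d[, k] <= offsets[jj[k]] + tol)
    active <- active[ok]
    j <- j + block
  }
  res <- logical(n)
  res[active] <- TRUE
  res
}

# deterministic scrambled facet order (golden-ratio stride)
facet_order <- function(nf) {
  if (nf <= 2L) return(seq_len(nf))
  order((seq_len(nf) * 0.6180339887498949) %% 1)
}

# Directed-edge -> face lookup of a hull (topology is rotation-invariant,
# so it is computed once per scene and reused every objective evaluation).
hull_topology <- function(hull) {
  f <- hull$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  list(edges = e, face_of = rep(seq_len(nrow(f)), 3),
       twin = match(paste(e[, 2], e[, 1]), paste(e[, 1], e[, 2])))
}

#' Tangent-cone facets of a hull seen from an exterior apex
#'
#' Computes the facet half-spaces of the (truncation-free) cone with apex
#' `apex` spanned by a convex hull: the intersection of the half-spaces
#' through the apex supported by the horizon edges of the hull as seen from
#' the apex. This is the solid the extended resection profile encloses
#' within the anatomy — the profile lines from the focal point through the
#' hull are extended beyond the farthest bone point, so counting voxels
#' inside the extended geometry is exactly counting them inside this cone.
#' No hull is rebuilt, and the construction is well conditioned for apexes
#' as far as -200000 mm (no quickhull on coordinates of mixed scale).
#'
#' If the apex lies on the hull boundary (focal point touching the tumor
#' base) the lateral facets degenerate to the hull's supporting facets at
#' the apex — the tangent cone of the hull at that point.
#'
#' @param verts hull vertex coordinates.
#' @param apex length-3 apex coordinates.
#' @param base list of `faces`, `normals`, `offsets` of the base hull in the
#'   same frame, with `faces` indexing rows of `verts`.
#' @param topo precomputed [hull_topology()] of the base hull.
#' @param interior a point interior to the base hull, same frame.
#' @param tol visibility tolerance.
#' @return list with `normals`, `offsets` of the cone half-spaces and
#'   `horizon` (ordered vertex-index cycle of the cone base; empty in the
#'   degenerate apex-on-hull case).
#' @keywords internal
cone_facets <- function(verts, apex, base, topo, interior, tol = 1e-9) {
  d <- as.vector(base$normals %*% apex) - base$offsets
  vis <- d > tol
  if (!any(vis)) {
    # apex on (or numerically inside) the hull: tangent cone at the apex
    supp <- abs(d) <= tol
    return(list(normals = base$normals[supp, , drop = FALSE],
                offsets = base$offsets[supp],
                horizon = integer(0)))
  }
  vis_edge <- vis[topo$face_of]
  hz_sel <- vis_edge & !vis[topo$face_of[topo$twin]]
  hz <- topo$edges[hz_sel, , drop = FALSE]
  # lateral facets (apex, a, b): outward normal checked against interior
  va <- verts[hz[, 1], , drop = FALSE]
  vb <- verts[hz[, 2], , drop = FALSE]
  nrm <- rowwise_cross(sweep(va, 2, apex), sweep(vb, 2, apex))
  len <- sqrt(rowSums(nrm^2))
  ok <- len > .Machine$double.eps
  nrm <- nrm[ok, , drop = FALSE] / len[ok]
  offs <- as.vector(nrm %*% apex)
  flip <- as.vector(nrm %*% interior) > offs
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  offs[flip] <- -offs[flip]
  list(normals = nrm, offsets = offs, horizon = order_cycle(hz))
}

# order directed horizon edges into a vertex cycle
order_cycle <- function(edges) {
  if (nrow(edges) == 0) return(integer(0))
  nxt <- edges[, 2]
  names(nxt) <- edges[, 1]
  cyc <- integer(nrow(edges))
  cyc[1] <- edges[1, 1]
  for (k in seq_len(nrow(edges) - 1)) {
    nx <- nxt[[as.character(cyc[k])]]
    if (is.null(nx)) break
    cyc[k + 1] <- nx
  }
  cyc[cyc != 0]
}

#' 2D convex polygon half-plane test
#'
#' Builds the 2D convex hull of generator points (delegated to
#' [grDevices::chull()]) and tests query points against its edge
#' half-planes; boundary within `tol` counts inside.
#'
#' @param points q x 2 matrix of query points.
#' @param generators g x 2 matrix of generator points.
#' @param tol membership tolerance.
#' @return Logical vector of length q.
#' @export
point_in_hull_2d <- function(points, generators, tol = 1e-9) {
  generators <- rbind(generators)
  idx <- grDevices::chull(generators[, 1], generators[, 2])
  if (length(idx) < 3) stop("degenerate hull: 2D generators are collinear")
  poly <- generators[idx, , drop = FALSE]   # chull returns clockwise order
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]
  ey <- b[, 2] - a[, 2]
  len <- sqrt(ex^2 + ey^2)
  points <- rbind(points)
  # signed distance to each edge; chull is clockwise => inside has s >= 0
  s <- outer(points[, 1], ey / len) - outer(points[, 2], ex / len)
  s <- sweep(s, 2, (a[, 1] * ey - a[, 2] * ex) / len)
  ok <- s[, 1] >= -tol
  for (j in seq_len(ncol(s))[-1]) ok <- ok & (s[, j] >= -tol)
  ok
}

#' @export
print.hull3d <- function(x, ...) {
  cat(sprintf("hull3d: %d hull vertices, %d facets\n",
              length(x$vertices), nrow(x$faces)))
  invisible(x)
}
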