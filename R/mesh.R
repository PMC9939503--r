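#' Triangulated surface mesh
#'
#' Constructs a watertight triangulated surface mesh in millimeter
#' coordinates. On construction the mesh is cleaned (duplicate vertices
#' merged, unreferenced vertices dropped, degenerate zero-area faces
#' removed), oriented so face windings give outward normals (positive
#' enclosed volume), and checked for watertightness: every undirected edge
#' must be shared by exactly two faces and every directed edge must appear
#' exactly once.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices, one
#'   triangle per row.
#' @param label optional `"bone"` or `"tumor"` tag.
#' @param clean merge duplicate vertices and drop degenerate faces first.
#' @param check enforce the watertightness invariant (error on failure).
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces`, `label`.
#' @seealso [load_mesh()], [write_mesh()], [mesh_volume()]
#' @export
surface_mesh <- function(vertices, faces, label = NULL,
                         clean = TRUE, check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (!is.null(label)) label <- match.arg(label, c("bone", "tumor"))
  if (clean) {
    merged <- merge_vertices(vertices, faces)
    vertices <- merged$vertices
    faces <- merged$faces
    faces <- drop_degenerate_faces(vertices, faces)
  }
  if (nrow(vertices) < 4) stop("mesh needs at least 4 vertices")
  m <- structure(list(vertices = vertices, faces = faces, label = label),
                 class = "surface_mesh")
  if (mesh_signed_volume(m) < 0) {
    m$faces <- m$faces[, c(1, 3, 2)]
  }
  if (check) check_watertight(m)
  m
}

# Merge exactly-coincident vertices (to 1e-9 mm) and reindex faces.
merge_vertices <- function(vertices, faces, digits = 9) {
  key <- paste(round(vertices[, 1], digits),
               round(vertices[, 2], digits),
               round(vertices[, 3], digits))
  first <- !duplicated(key)
  new_id <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(new_id[faces], ncol = 3))
}

drop_degenerate_faces <- function(vertices, faces) {
  repeated <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!repeated, , drop = FALSE]
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  area2 <- rowSums(rowwise_cross(e1, e2)^2)
  scale <- max(abs(vertices), 1)
  faces[area2 > (1e-12 * scale^2)^2, , drop = FALSE]
}

#' Watertightness check
#'
#' Asserts that every undirected edge of the mesh is shared by exactly two
#' faces and that directed edges pair up (consistent orientation). An open
#' (boundary) edge count of zero is required.
#'
#' @param mesh a [surface_mesh()] (or a bare vertices/faces list).
#' @return Invisibly, a list with `open_edges` (edges used by exactly one
#'   face) and `nonmanifold_edges` (edges used by three or more faces).
#' @export
check_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  undirected <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(undirected)
  open_edges <- sum(cnt == 1)
  nonmanifold <- sum(cnt > 2)
  if (open_edges > 0 || nonmanifold > 0) {
    stop(sprintf("mesh is not watertight: %d open edge(s), %d non-manifold edge(s)",
                 open_edges, nonmanifold), call. = FALSE)
  }
  directed <- paste(e[, 1], e[, 2])
  if (anyDuplicated(directed)) {
    stop("mesh is not consistently oriented: repeated directed edge", call. = FALSE)
  }
  invisible(list(open_edges = open_edges, nonmanifold_edges = nonmanifold))
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * rowwise_cross(b, cc))) / 6
}

#' Mesh volume, centroid and Euler characteristic
#'
#' `mesh_volume()` is the enclosed volume (divergence theorem; positive for
#' outward-oriented watertight meshes). `mesh_centroid()` is the vertex mean,
#' the point the scene is centered on. `euler_characteristic()` is
#' V - E + F (2 for a closed genus-0 surface).
#'
#' @param mesh a [surface_mesh()].
#' @return A scalar.
#' @export
mesh_volume <- function(mesh) abs(mesh_signed_volume(mesh))

#' @rdname mesh_volume
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' @rdname mesh_volume
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  n_edges <- length(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(mesh$vertices) - n_edges + nrow(f)
}

#' Rigidly translate a mesh
#' @param mesh a [surface_mesh()].
#' @param offset length-3 translation (mm), added to every vertex.
#' @return The translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, `+`)
  mesh
}

#' Uniform margin expansion of a tumor mesh
#'
#' Scales the mesh about its vertex centroid by `margin_scale` >= 1,
#' emulating the inclusion of a cuff of healthy tissue in the resection
#' target: the enlarged mesh, not the raw tumor, then drives the resection
#' geometry. For any mesh star-shaped about its centroid the expansion
#' contains the original solid.
#'
#' @param tumor a [surface_mesh()] (normally labelled `"tumor"`).
#' @param margin_scale dimensionless scale factor, >= 1.
#' @return The expanded mesh; the caller keeps the original for reporting.
#' @export
expand_margin <- function(tumor, margin_scale) {
  if (!is.numeric(margin_scale) || length(margin_scale) != 1 ||
      is.na(margin_scale) || margin_scale < 1) {
    stop("margin_scale must be a single number >= 1")
  }
  if (margin_scale == 1) return(tumor)
  ctr <- mesh_centroid(tumor)
  tumor$vertices <- sweep(sweep(tumor$vertices, 2, ctr, `-`) * margin_scale,
                          2, ctr, `+`)
  tumor
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh%s: %d vertices, %d faces, volume %.1f mm^3\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}
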