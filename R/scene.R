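#' Assemble a bone/tumor scene
#'
#' Bundles the two surface meshes with their labeled voxel model and caches
#' the tumor convex hull (vertex coordinates, facet planes and edge
#' topology). The hull cache is what makes repeated resection-geometry
#' evaluations cheap: rigid motions transform the cached facet planes
#' directly instead of recomputing the hull.
#'
#' @param bone_mesh,tumor_mesh watertight [surface_mesh()] objects.
#' @param voxels a `voxel_model` from [voxelize()]; built here if `NULL`.
#' @param pitch grid pitch used if `voxels` is `NULL`.
#' @return An object of class `scene`.
#' @export
scene <- function(bone_mesh, tumor_mesh, voxels = NULL, pitch = 2) {
  if (is.null(voxels)) voxels <- voxelize(bone_mesh, tumor_mesh, pitch)
  sc <- structure(list(bone_mesh = bone_mesh, tumor_mesh = tumor_mesh,
                       voxels = voxels, centered = FALSE, analytic = NULL),
                  class = "scene")
  refresh_hull_cache(sc)
}

refresh_hull_cache <- function(sc) {
  hull <- convex_hull_3d(sc$tumor_mesh$vertices)
  # re-index hull faces into the compact hull-vertex list
  vid <- hull$vertices
  remap <- match(as.vector(hull$faces), vid)
  sc$tumor_hull <- list(
    verts = hull$points[vid, , drop = FALSE],
    faces = matrix(remap, ncol = 3),
    normals = hull$normals, offsets = hull$offsets,
    interior = hull$interior)
  sc$tumor_hull$topo <- hull_topology(list(faces = sc$tumor_hull$faces))
  sc
}

#' Center the scene on the tumor centroid
#'
#' Translates the bone and tumor meshes and every voxel set so the tumor
#' surface-mesh centroid (vertex mean) is at the origin, retaining the
#' original relative alignment. Resection parameters are defined in this
#' tumor-centered base frame. Idempotent.
#'
#' @param sc a [scene()].
#' @return The centered scene; the applied translation accumulates in
#'   `sc$voxels$origin_offset`.
#' @export
center_on_tumor <- function(sc) {
  stopifnot(inherits(sc, "scene"))
  ctr <- mesh_centroid(sc$tumor_mesh)
  sc$bone_mesh <- translate_mesh(sc$bone_mesh, -ctr)
  sc$tumor_mesh <- translate_mesh(sc$tumor_mesh, -ctr)
  vx <- sc$voxels
  for (nm in c("healthy_bone", "intracortical_tumor", "extraosseous_tumor")) {
    if (nrow(vx[[nm]])) vx[[nm]] <- sweep(vx[[nm]], 2, ctr)
  }
  vx$origin <- vx$origin - ctr
  vx$origin_offset <- vx$origin_offset - ctr
  sc$voxels <- vx
  sc$centered <- TRUE
  refresh_hull_cache(sc)
}

#' @export
print.scene <- function(x, ...) {
  cat("scene", if (isTRUE(x$centered)) "(tumor-centered)" else "", "\n")
  print(x$bone_mesh)
  print(x$tumor_mesh)
  print(x$voxels)
  invisible(x)
}
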