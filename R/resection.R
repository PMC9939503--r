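#' Resection-geometry parameter vector
#'
#' The conical and flat-based hulls take six parameters: rotations about
#' the base z-, y- and x-axes (degrees, applied in that order,
#' extrinsic), then a translation `(t_x, t_y, t_z)` of the focal point
#' expressed in the rotated local frame (mm). The contoured hull takes a
#' seventh parameter `phi_z`, an extra rotation about the local z-axis
#' (degrees). Bounds: rotations within +/-180 degrees, `t_x`/`t_y` within
#' the rotated tumor x/y extents, `t_z` in `[-200000, min(T_z)]` (the huge
#' lower bound acts as "focal point at infinity": a quasi-cylindrical
#' resection), `phi_z` within +/-90 degrees. `t_x`/`t_y`/`t_z` are clamped
#' to the rotated tumor extents at evaluation time, since those bounds
#' move with the rotation parameters.
#'
#' @param theta_z,theta_y,theta_x base-axis rotations, degrees.
#' @param t_x,t_y,t_z local-frame translation of the focal point, mm.
#' @param phi_z local z rotation, degrees (contoured only).
#' @param rg_type `"conical"`, `"flat"` or `"contoured"`.
#' @return An object of class `rg_params`.
#' @export
rg_params <- function(theta_z, theta_y, theta_x, t_x, t_y, t_z,
                      phi_z = NULL,
                      rg_type = c("conical", "flat", "contoured")) {
  rg_type <- match.arg(rg_type)
  if (rg_type == "contoured" && is.null(phi_z)) {
    stop("contoured resection requires phi_z")
  }
  if (rg_type != "contoured" && !is.null(phi_z)) {
    stop("phi_z is only meaningful for the contoured resection")
  }
  ang <- c(theta_z, theta_y, theta_x)
  if (any(!is.finite(ang)) || any(abs(ang) > 180 + 1e-9)) {
    stop("base rotations must lie within +/-180 degrees")
  }
  if (!is.null(phi_z) && abs(phi_z) > 90 + 1e-9) {
    stop("phi_z must lie within +/-90 degrees")
  }
  if (!is.finite(t_z) || t_z < -200000 - 1e-6) {
    stop("t_z must be >= -200000 mm")
  }
  structure(list(theta_z = theta_z, theta_y = theta_y, theta_x = theta_x,
                 t_x = t_x, t_y = t_y, t_z = t_z, phi_z = phi_z,
                 rg_type = rg_type),
            class = "rg_params")
}

#' Convert between parameter objects and bare numeric vectors
#'
#' `params_vector()` flattens an [rg_params()] to the optimizer's numeric
#' vector (length 6, or 7 for contoured); `vector_params()` is its inverse.
#'
#' @param p an [rg_params()].
#' @return `params_vector()`: a numeric vector; `vector_params()`: an
#'   [rg_params()].
#' @export
params_vector <- function(p) {
  v <- c(p$theta_z, p$theta_y, p$theta_x, p$t_x, p$t_y, p$t_z)
  if (p$rg_type == "contoured") v <- c(v, p$phi_z)
  v
}

#' @rdname params_vector
#' @param x numeric vector of length 6 (or 7 for contoured).
#' @param rg_type `"conical"`, `"flat"` or `"contoured"`.
#' @export
vector_params <- function(x, rg_type) {
  rg_params(x[1], x[2], x[3], x[4], x[5], x[6],
            phi_z = if (rg_type == "contoured") x[7] else NULL,
            rg_type = rg_type)
}

#' Transform a scene into the local resection frame
#'
#' Applies the parameter rotation and translation so the focal point is at
#' the local origin: `x_local = Rz(phi_z) (R x - t)` with
#' `R = Rx Ry Rz`. With `t_z <= min(T_z)` the tumor's lowest point sits at
#' height `min(T_z) - t_z >= 0` above the focal point.
#'
#' @param sc a centered [scene()].
#' @param params an [rg_params()].
#' @return List of transformed point sets: `bone_vertices`,
#'   `tumor_vertices`, `healthy_bone`, `intracortical_tumor`,
#'   `extraosseous_tumor`, plus the applied `rotation`, clamped
#'   `translation`, and `focal_point_base` (focal point in base frame).
#' @export
to_local <- function(sc, params) {
  stopifnot(inherits(sc, "scene"), inherits(params, "rg_params"))
  R <- rg_rotation(params$theta_z, params$theta_y, params$theta_x)
  t_clamped <- clamp_translation(sc, R, params)
  Q <- if (!is.null(params$phi_z)) rot_z(params$phi_z) else diag(3)
  M <- Q %*% R
  tq <- as.vector(Q %*% t_clamped)
  tf <- function(pts) {
    if (is.null(pts) || nrow(pts) == 0) return(pts)
    sweep(pts %*% t(M), 2, tq)
  }
  list(bone_vertices = tf(sc$bone_mesh$vertices),
       tumor_vertices = tf(sc$tumor_mesh$vertices),
       healthy_bone = tf(sc$voxels$healthy_bone),
       intracortical_tumor = tf(sc$voxels$intracortical_tumor),
       extraosseous_tumor = tf(sc$voxels$extraosseous_tumor),
       rotation = R, translation = t_clamped,
       phi_z = params$phi_z,
       focal_point_base = as.vector(t(R) %*% t_clamped))
}

# clamp (t_x, t_y) to the rotated tumor x/y extents and t_z to
# [-200000, min rotated tumor z]; the static PSO box is wider than the
# rotation-dependent table bounds, so every evaluation clamps
clamp_translation <- function(sc, R, params) {
  hv <- sc$tumor_hull$verts %*% t(R)
  c(min(max(params$t_x, min(hv[, 1])), max(hv[, 1])),
    min(max(params$t_y, min(hv[, 2])), max(hv[, 2])),
    max(min(params$t_z, min(hv[, 3])), -200000))
}

#' Bone-waste metric
#'
#' `100 * removed / (removed + intracortical)`: collaterally resected
#' healthy bone as a percentage of the total resected intracortical volume.
#' Counts may be voxel counts or volumes (the ratio is scale-free at fixed
#' pitch).
#'
#' @param removed_count healthy-bone voxels inside the resection geometry.
#' @param intracortical_count tumor voxels inside the bone envelope.
#' @return Percentage in `[0, 100)`.
#' @export
bone_waste <- function(removed_count, intracortical_count) {
  if (intracortical_count <= 0) {
    stop("bone waste undefined: intracortical tumor volume is zero")
  }
  100 * removed_count / (removed_count + intracortical_count)
}

# ---- core evaluation ----------------------------------------------------

#' Evaluate a resection geometry (fast path)
#'
#' Computes the removed healthy-bone voxel set for one parameter vector
#' without building profile loops or export structures — the objective the
#' optimizer iterates on. Removed = healthy bone inside the focal-point
#' cone spanned by the tumor hull (the solid enclosed by the extended cut
#' profile), further cut by the facing plane (flat) or the local-xz
#' profile prism (contoured). The cached tumor-hull facets are transformed
#' rigidly (normals rotate, offsets shift) rather than recomputed, and the
#' cone comes from the horizon construction, so one evaluation costs a few
#' small matrix products plus the voxel half-space test.
#'
#' @param sc a centered [scene()].
#' @param params an [rg_params()].
#' @param tol membership tolerance (mm); boundary ties favor resection.
#' @param with_masks also classify the intracortical tumor voxels
#'   (`intracortical_mask`), for completeness checks.
#' @return List with `removed` (row indices into
#'   `sc$voxels$healthy_bone`), `removed_count`, `intracortical_count`,
#'   the applied transform, and the local-frame hull/cone geometry.
#' @export
evaluate_rg <- function(sc, params, tol = 1e-9, with_masks = FALSE) {
  stopifnot(inherits(sc, "scene"), inherits(params, "rg_params"))
  th <- sc$tumor_hull
  R <- rg_rotation(params$theta_z, params$theta_y, params$theta_x)
  t_clamped <- clamp_translation(sc, R, params)
  Q <- if (!is.null(params$phi_z)) rot_z(params$phi_z) else NULL
  M <- if (is.null(Q)) R else Q %*% R
  tq <- if (is.null(Q)) t_clamped else as.vector(Q %*% t_clamped)

  hv <- sweep(th$verts %*% t(M), 2, tq)          # hull vertices, local
  nrm <- th$normals %*% t(M)                     # facet normals, local
  offs <- th$offsets - as.vector((th$normals %*% t(R)) %*% t_clamped)
  interior <- as.vector(M %*% th$interior) - tq
  cone <- cone_facets(hv, c(0, 0, 0),
                      list(faces = th$faces, normals = nrm, offsets = offs),
                      th$topo, interior, tol = tol)

  B <- sc$voxels$healthy_bone
  Bl <- sweep(B %*% t(M), 2, tq)
  zmin_t <- min(hv[, 3])
  # the cone never reaches below its apex (z = 0): cheap prefilter
  cand <- which(Bl[, 3] >= -tol)
  if (params$rg_type == "flat") {
    cand <- cand[Bl[cand, 3] > zmin_t - tol]     # facing cut, ties removed
  }
  mask <- hull_mask(Bl[cand, , drop = FALSE], cone$normals, cone$offsets, tol)
  removed <- cand[mask]
  if (params$rg_type == "contoured") {
    in2d <- point_in_hull_2d(Bl[removed, c(1, 3), drop = FALSE],
                             hv[, c(1, 3)], tol = tol)
    removed <- removed[in2d]
  }
  out <- list(removed = removed,
              removed_count = length(removed),
              intracortical_count = nrow(sc$voxels$intracortical_tumor),
              rotation = R, translation = t_clamped, phi_z = params$phi_z,
              local_hull_verts = hv, cone = cone, zmin_tumor = zmin_t,
              M = M, tq = tq)
  if (with_masks) {
    Ti <- sc$voxels$intracortical_tumor
    if (nrow(Ti)) {
      Tl <- sweep(Ti %*% t(M), 2, tq)
      m <- hull_mask(Tl, cone$normals, cone$offsets, tol)
      if (params$rg_type == "flat") m <- m & (Tl[, 3] > zmin_t - tol)
      if (params$rg_type == "contoured") {
        m <- m & point_in_hull_2d(Tl[, c(1, 3), drop = FALSE],
                                  hv[, c(1, 3)], tol = tol)
      }
      out$intracortical_mask <- m
    } else {
      out$intracortical_mask <- logical(0)
    }
  }
  out
}

#' Build a resection geometry
#'
#' Realizes the conical, flat-based or contoured hull resection for one
#' parameter vector: the removed healthy-bone voxel set, the bone-waste
#' value, the focal point, and the cut-surface profile loops mapped back to
#' base coordinates. The removed set is the healthy bone enclosed by the
#' extended cut surface — the cone from the focal point spanned by the
#' tumor hull — so it is independent of how far the exported profile is
#' extended (see [extend_profile()]): membership in the cone depends only
#' on direction from the focal point.
#'
#' @param sc a centered [scene()].
#' @param params an [rg_params()].
#' @param extend extend the profile for en-bloc extractability.
#' @param clearance extension clearance beyond the farthest in-cone point, mm.
#' @return An object of class `resection_geometry`: `rg_type`, `params`
#'   (with the evaluation-time clamped translation), `focal_point` (base
#'   frame), `profile_3d` (list of ordered base-frame loops: tumor-level
#'   horizon loop and, if extended, the extended outer loop),
#'   `facing_profile` (ordered loop of the flat facing cut, or the local-xz
#'   hull polygon for the contoured cut; `NULL` for conical),
#'   `removed_indices` (rows of `sc$voxels$healthy_bone`),
#'   `removed_volume` (mm^3), and `waste` (a `waste_result`).
#' @export
build_resection <- function(sc, params, extend = TRUE, clearance = 5) {
  ev <- evaluate_rg(sc, params)
  pitch <- sc$voxels$pitch
  to_base <- function(pts) {
    if (is.null(pts) || nrow(pts) == 0) return(pts)
    sweep(pts, 2, ev$tq, `+`) %*% ev$M        # inverse of x_l = M x - tq
  }
  hz <- ev$cone$horizon
  loops <- list()
  if (length(hz) >= 3) {
    loops$horizon <- to_base(ev$local_hull_verts[hz, , drop = FALSE])
  }
  facing <- NULL
  if (params$rg_type == "flat" && length(hz) >= 3) {
    # intersect each apex->horizon-vertex ray with the plane z = zmin
    hvz <- ev$local_hull_verts[hz, , drop = FALSE]
    s <- ev$zmin_tumor / pmax(hvz[, 3], .Machine$double.eps)
    facing <- to_base(hvz * s)
  } else if (params$rg_type == "contoured") {
    g <- ev$local_hull_verts[, c(1, 3)]
    idx <- grDevices::chull(g[, 1], g[, 2])
    poly <- g[idx, , drop = FALSE]
    facing <- to_base(cbind(poly[, 1], 0, poly[, 2]))
  }
  waste <- structure(list(
    bone_waste_pct = bone_waste(ev$removed_count, ev$intracortical_count),
    removed_count = ev$removed_count,
    intracortical_count = ev$intracortical_count,
    extraosseous_count = nrow(sc$voxels$extraosseous_tumor),
    bone_waste_pct_whole_tumor = 100 * ev$removed_count /
      (ev$removed_count + ev$intracortical_count +
         nrow(sc$voxels$extraosseous_tumor))),
    class = "waste_result")
  rg <- structure(list(rg_type = params$rg_type, params = params,
                       focal_point = as.vector(t(ev$rotation) %*% ev$translation),
                       profile_3d = loops, facing_profile = facing,
                       removed_indices = ev$removed,
                       removed_volume = ev$removed_count * pitch^3,
                       waste = waste,
                       local = list(M = ev$M, tq = ev$tq,
                                    hull_verts = ev$local_hull_verts,
                                    horizon = hz, zmin_tumor = ev$zmin_tumor,
                                    cone = ev$cone)),
                  class = "resection_geometry")
  if (extend) rg <- extend_profile(rg, sc, clearance = clearance)
  rg
}

#' Extend the cut profile for en-bloc extractability
#'
#' Lengthens each focal-point-to-profile ray until the exported cut surface
#' clears the farthest bone or tumor point lying inside the cone, plus a
#' clearance, so the resected volume can be withdrawn without further cuts.
#' The removed-voxel count is untouched: cone membership depends only on
#' direction from the focal point, not on the profile's exported length.
#'
#' @param rg a [build_resection()] result.
#' @param sc the scene it was built on.
#' @param clearance clearance beyond the farthest in-cone point, mm.
#' @return `rg` with an `extended` loop added to `profile_3d` and the
#'   reach distance recorded in `rg$extension`.
#' @export
extend_profile <- function(rg, sc, clearance = 5) {
  stopifnot(inherits(rg, "resection_geometry"))
  loc <- rg$local
  hz <- loc$horizon
  if (length(hz) < 3) return(rg)
  tf <- function(pts) sweep(pts %*% t(loc$M), 2, loc$tq)
  B <- sc$voxels$healthy_bone[rg$removed_indices, , drop = FALSE]
  pts <- rbind(loc$hull_verts, if (nrow(B)) tf(B))
  dmax <- sqrt(max(rowSums(pts^2)))             # farthest in-cone point from FP
  reach <- dmax + clearance
  hvz <- loc$hull_verts[hz, , drop = FALSE]
  len <- sqrt(rowSums(hvz^2))
  fac <- pmax(1, reach / pmax(len, .Machine$double.eps))
  ext_local <- hvz * fac
  rg$profile_3d$extended <- sweep(ext_local, 2, loc$tq, `+`) %*% loc$M
  rg$extension <- list(reach = reach, clearance = clearance, dmax = dmax)
  rg
}

#' Planar resection baseline
#'
#' The comparator for the hull-type geometries: a single planar cut with
#' unit normal `n` removing the half-space `n . x >= offset`. The plane
#' must separate: every tumor voxel strictly on the removed side.
#'
#' @param sc a centered [scene()].
#' @param normal length-3 plane normal (normalized internally).
#' @param offset plane offset (mm): the cut is `n . x = offset`.
#' @return A `waste_result` (as in [build_resection()]).
#' @export
planar_baseline <- function(sc, normal, offset) {
  stopifnot(inherits(sc, "scene"))
  n <- normal / sqrt(sum(normal^2))
  tum <- rbind(sc$voxels$intracortical_tumor, sc$voxels$extraosseous_tumor)
  if (nrow(tum) && min(tum %*% n) <= offset) {
    stop("infeasible plane: it does not strictly separate the tumor voxels")
  }
  removed <- sum(sc$voxels$healthy_bone %*% n >= offset)
  intra <- nrow(sc$voxels$intracortical_tumor)
  extra <- nrow(sc$voxels$extraosseous_tumor)
  structure(list(bone_waste_pct = bone_waste(removed, intra),
                 removed_count = removed, intracortical_count = intra,
                 extraosseous_count = extra,
                 bone_waste_pct_whole_tumor =
                   100 * removed / (removed + intra + extra)),
            class = "waste_result")
}

#' Best planar baseline by grid search
#'
#' Searches cut-plane normals on an icosphere direction grid; for each
#' normal the plane is placed as close to the tumor as feasibility allows
#' (just below the minimum tumor-mesh projection). Returns the
#' least-wasteful feasible plane.
#'
#' @param sc a centered [scene()].
#' @param subdivisions icosphere subdivision level for the normal grid.
#' @param delta standoff of the plane below the tumor (mm).
#' @return List with `waste` (a `waste_result`), `normal`, `offset`;
#'   or `NULL` if no direction yields a feasible separating plane.
#' @export
best_planar_baseline <- function(sc, subdivisions = 1, delta = 1e-6) {
  dirs <- sphere_directions(subdivisions)
  tumv <- sc$tumor_mesh$vertices
  best <- NULL
  for (i in seq_len(nrow(dirs))) {
    n <- dirs[i, ]
    offset <- min(tumv %*% n) - delta
    w <- tryCatch(planar_baseline(sc, n, offset), error = function(e) NULL)
    if (is.null(w)) next
    if (is.null(best) || w$bone_waste_pct < best$waste$bone_waste_pct) {
      best <- list(waste = w, normal = n, offset = offset)
    }
  }
  best
}

#' @export
print.waste_result <- function(x, ...) {
  cat(sprintf(paste0("bone waste %.2f%% (%d healthy voxels removed, ",
                     "%d intracortical tumor voxels)\n"),
              x$bone_waste_pct, x$removed_count, x$intracortical_count))
  invisible(x)
}

#' @export
print.resection_geometry <- function(x, ...) {
  cat(sprintf("%s hull resection: removed volume %.1f mm^3\n",
              x$rg_type, x$removed_volume))
  print(x$waste)
  invisible(x)
}

#' Export a resection geometry's cut surface
#'
#' Writes the profile loops as ordered-point CSV files and, for geometries
#' with a closed horizon loop, a triangulated cut surface (cone panels from
#' the focal point to the extended profile, plus the facing polygon for the
#' flat-based cut) as ASCII PLY.
#'
#' @param rg a [build_resection()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
export_resection <- function(rg, dir, prefix = rg$rg_type) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in names(rg$profile_3d)) {
    p <- file.path(dir, sprintf("%s_profile_%s.csv", prefix, nm))
    utils::write.csv(as.data.frame(rg$profile_3d[[nm]]), p, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(rg$facing_profile)) {
    p <- file.path(dir, sprintf("%s_facing_profile.csv", prefix))
    utils::write.csv(as.data.frame(rg$facing_profile), p, row.names = FALSE)
    written <- c(written, p)
  }
  p <- file.path(dir, sprintf("%s_removed_voxels.csv", prefix))
  utils::write.csv(data.frame(index = rg$removed_indices), p, row.names = FALSE)
  written <- c(written, p)
  loop <- rg$profile_3d$extended
  if (is.null(loop)) loop <- rg$profile_3d$horizon
  if (!is.null(loop) && nrow(loop) >= 3) {
    k <- nrow(loop)
    apexv <- rbind(rg$focal_point)
    verts <- rbind(apexv, loop)
    panels <- cbind(1L, 1L + seq_len(k), 1L + c(2:k, 1))
    mesh <- structure(list(vertices = verts, faces = panels, label = NULL),
                      class = "surface_mesh")
    p <- file.path(dir, sprintf("%s_cut_surface.ply", prefix))
    write_ply_ascii(mesh, p)
    written <- c(written, p)
  }
  invisible(written)
}
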