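#' Classify grid points against a watertight mesh by ray casting
#'
#' Casts an axis-parallel ray (along +z) through every (x, y) column of the
#' grid, collects ray/triangle crossings, and classifies each grid center by
#' crossing parity. A center whose z lies within `tol` of a surface crossing
#' counts as inside (ties favor resection completeness). Columns whose ray
#' passes within numerical tolerance of a triangle edge or vertex, or
#' through a ray-parallel facet, are re-cast with a small deterministic
#' in-plane perturbation until unambiguous.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param xs,ys,zs grid center coordinates along each axis (mm).
#' @param tol on-surface tolerance (mm).
#' @return Logical array of dim `c(length(xs), length(ys), length(zs))`.
#' @keywords internal
classify_grid <- function(mesh, xs, ys, zs, tol = 1e-9) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  inside <- array(FALSE, c(nx, ny, nz))
  cross <- column_crossings(mesh, xs, ys)
  ambiguous <- cross$ambiguous
  # parity-classify unambiguous columns
  for (cid in setdiff(names(cross$z), ambiguous)) {
    ij <- as.integer(strsplit(cid, ",")[[1]])
    zc <- sort(cross$z[[cid]])
    below <- findInterval(zs, zc)
    on_surf <- vapply(zs, function(z) any(abs(z - zc) <= tol), TRUE)
    inside[ij[1], ij[2], ] <- (below %% 2L == 1L) | on_surf
  }
  # re-cast ambiguous columns with perturbed rays
  if (length(ambiguous)) {
    jitter_dirs <- cbind(c(1, 2), c(-2, 1), c(1, -1), c(3, 1), c(-1, -3))
    pitch <- if (nx > 1) diff(xs[1:2]) else if (ny > 1) diff(ys[1:2]) else 1
    for (cid in ambiguous) {
      ij <- as.integer(strsplit(cid, ",")[[1]])
      p0 <- c(xs[ij[1]], ys[ij[2]])
      done <- FALSE
      for (k in seq_len(ncol(jitter_dirs) * 3)) {
        eps <- 1e-6 * pitch * ceiling(k / ncol(jitter_dirs))
        d <- jitter_dirs[, ((k - 1) %% ncol(jitter_dirs)) + 1]
        res <- single_column_crossings(mesh, p0[1] + eps * d[1],
                                       p0[2] + eps * d[2])
        if (!res$ambiguous) {
          zc <- sort(res$z)
          below <- findInterval(zs, zc)
          on_surf <- vapply(zs, function(z) any(abs(z - zc) <= tol), TRUE)
          inside[ij[1], ij[2], ] <- (below %% 2L == 1L) | on_surf
          done <- TRUE
          break
        }
      }
      if (!done) {
        warning("ray casting remained ambiguous for a column; using last parity")
        zc <- sort(cross$z[[cid]])
        below <- findInterval(zs, zc)
        inside[ij[1], ij[2], ] <- below %% 2L == 1L
      }
    }
  }
  inside
}

# All z-crossings per (x,y) grid column, plus the ids of ambiguous columns.
column_crossings <- function(mesh, xs, ys, bary_tol = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  nx <- length(xs); ny <- length(ys)
  ax <- v[f[, 1], 1]; ay <- v[f[, 1], 2]; az <- v[f[, 1], 3]
  bx <- v[f[, 2], 1]; by <- v[f[, 2], 2]; bz <- v[f[, 2], 3]
  cx <- v[f[, 3], 1]; cy <- v[f[, 3], 2]; cz <- v[f[, 3], 3]
  den <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)  # 2 * projected area
  scale2 <- max(abs(v[, 1:2]), 1)^2
  col_ids <- vector("list", nrow(f))
  z_hits <- vector("list", nrow(f))
  amb <- character()
  for (t in seq_len(nrow(f))) {
    ix <- which(xs >= min(ax[t], bx[t], cx[t]) - 1e-12 &
                xs <= max(ax[t], bx[t], cx[t]) + 1e-12)
    iy <- which(ys >= min(ay[t], by[t], cy[t]) - 1e-12 &
                ys <= max(ay[t], by[t], cy[t]) + 1e-12)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    cids <- paste0(rep(ix, times = length(iy)), ",", rep(iy, each = length(ix)))
    if (abs(den[t]) < 1e-12 * scale2) {
      # ray-parallel facet: any column over its footprint is ambiguous
      amb <- c(amb, cids)
      next
    }
    w1 <- ((bx[t] - px) * (cy[t] - py) - (by[t] - py) * (cx[t] - px)) / den[t]
    w2 <- ((cx[t] - px) * (ay[t] - py) - (cy[t] - py) * (ax[t] - px)) / den[t]
    w3 <- 1 - w1 - w2
    wmin <- pmin(w1, w2, w3)
    hit <- wmin > -bary_tol
    if (!any(hit)) next
    edge <- hit & (wmin < bary_tol)
    if (any(edge)) amb <- c(amb, cids[edge])
    zc <- w1[hit] * az[t] + w2[hit] * bz[t] + w3[hit] * cz[t]
    col_ids[[t]] <- cids[hit]
    z_hits[[t]] <- zc
  }
  all_ids <- unlist(col_ids)
  all_z <- unlist(z_hits)
  list(z = split(all_z, all_ids), ambiguous = unique(amb))
}

# crossings of one perturbed ray (px, py); ambiguous if it grazes an edge
single_column_crossings <- function(mesh, px, py, bary_tol = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  den <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
         (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  scale2 <- max(abs(v[, 1:2]), 1)^2
  flat <- abs(den) < 1e-12 * scale2
  den[flat] <- 1
  w1 <- ((b[, 1] - px) * (cc[, 2] - py) - (b[, 2] - py) * (cc[, 1] - px)) / den
  w2 <- ((cc[, 1] - px) * (a[, 2] - py) - (cc[, 2] - py) * (a[, 1] - px)) / den
  w3 <- 1 - w1 - w2
  wmin <- pmin(w1, w2, w3)
  hit <- !flat & wmin > -bary_tol
  ambiguous <- any(hit & wmin < bary_tol)
  zc <- w1[hit] * a[hit, 3] + w2[hit] * b[hit, 3] + w3[hit] * cc[hit, 3]
  list(z = zc, ambiguous = ambiguous)
}

#' Point-in-mesh test by ray casting
#'
#' Classifies arbitrary points against a watertight mesh with the same
#' parity rule used by [voxelize()] (boundary within `tol` counts inside).
#'
#' @param points n x 3 matrix (mm).
#' @param mesh a watertight [surface_mesh()].
#' @param tol on-surface tolerance (mm).
#' @return Logical vector of length n.
#' @export
points_in_mesh <- function(points, mesh, tol = 1e-9) {
  points <- rbind(points)
  out <- logical(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    res <- single_column_crossings(mesh, p[1], p[2])
    k <- 0
    while (res$ambiguous && k < 12) {
      k <- k + 1
      res <- single_column_crossings(mesh, p[1] + k * 1e-7 * (k %% 3 + 1),
                                     p[2] + k * 2.3e-7)
    }
    zc <- res$z
    out[i] <- any(abs(p[3] - zc) <= tol) || (sum(zc < p[3]) %% 2L == 1L)
  }
  out
}

#' Voxelize a bone/tumor scene
#'
#' Embeds the two watertight meshes in a uniform cubic grid (default 2 mm
#' pitch, coordinates at cube centers) spanning their joint axis-aligned
#' bounds, with the grid anchored so the minimum corner of the joint
#' bounding box is a cube corner. Each center is classified against both
#' meshes by ray-crossing parity; centers outside both meshes are
#' discarded, and bone centers falling inside the tumor mesh are moved out
#' of the healthy-bone set — they constitute the intracortical tumor.
#'
#' @param bone,tumor watertight [surface_mesh()] objects in a shared mm frame.
#' @param pitch cubic grid spacing in mm (default 2).
#' @return An object of class `voxel_model`: list with `pitch`, `origin`
#'   (grid minimum corner), `origin_offset` (translation applied so far,
#'   see [center_on_tumor()]), and the three pairwise-disjoint center sets
#'   `healthy_bone`, `intracortical_tumor`, `extraosseous_tumor`
#'   (n x 3 matrices, mm).
#' @export
voxelize <- function(bone, tumor, pitch = 2) {
  stopifnot(inherits(bone, "surface_mesh"), inherits(tumor, "surface_mesh"),
            is.numeric(pitch), pitch > 0)
  lo <- pmin(apply(bone$vertices, 2, min), apply(tumor$vertices, 2, min))
  hi <- pmax(apply(bone$vertices, 2, max), apply(tumor$vertices, 2, max))
  n <- pmax(1L, as.integer(ceiling((hi - lo) / pitch)))
  xs <- lo[1] + pitch * (seq_len(n[1]) - 0.5)
  ys <- lo[2] + pitch * (seq_len(n[2]) - 0.5)
  zs <- lo[3] + pitch * (seq_len(n[3]) - 0.5)
  in_bone <- classify_grid(bone, xs, ys, zs)
  in_tumor <- classify_grid(tumor, xs, ys, zs)
  centers <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    cbind(x = xs[idx[, 1]], y = ys[idx[, 2]], z = zs[idx[, 3]])
  }
  healthy <- centers(in_bone & !in_tumor)
  intra <- centers(in_bone & in_tumor)
  extra <- centers(!in_bone & in_tumor)
  if (nrow(healthy) == 0) stop("degenerate scene: no healthy bone voxels")
  if (nrow(intra) + nrow(extra) == 0) stop("degenerate scene: no tumor voxels")
  structure(list(pitch = pitch, origin = lo, origin_offset = c(0, 0, 0),
                 healthy_bone = healthy, intracortical_tumor = intra,
                 extraosseous_tumor = extra),
            class = "voxel_model")
}

#' Voxel-model volumes
#'
#' Voxel-count volume estimates (count times pitch cubed) of healthy bone,
#' intracortical tumor and extraosseous tumor. Both bone-waste denominator
#' conventions can be formed from these: the intracortical-only convention
#' used by the optimizer, and the whole-tumor convention
#' (intracortical + extraosseous).
#'
#' @param voxels a `voxel_model`.
#' @return Named numeric vector of volumes in mm^3.
#' @export
voxel_volumes <- function(voxels) {
  v <- voxels$pitch^3
  c(healthy_bone = nrow(voxels$healthy_bone) * v,
    intracortical_tumor = nrow(voxels$intracortical_tumor) * v,
    extraosseous_tumor = nrow(voxels$extraosseous_tumor) * v)
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf(paste0("voxel_model: pitch %g mm; %d healthy bone, ",
                     "%d intracortical tumor, %d extraosseous tumor centers\n"),
              x$pitch, nrow(x$healthy_bone), nrow(x$intracortical_tumor),
              nrow(x$extraosseous_tumor)))
  invisible(x)
}

#' Write / read a voxel model as a columnar table
#'
#' Serializes the labeled centers as columns `x, y, z, label` to CSV
#' (gzip-compressed when the path ends in `.gz`).
#'
#' @param voxels a `voxel_model`.
#' @param path output path (`.csv` or `.csv.gz`).
#' @return `path` (write) or a `voxel_model` (read).
#' @export
write_voxels <- function(voxels, path) {
  as_rows <- function(m, lbl) {
    if (nrow(m) == 0) return(NULL)
    data.frame(x = m[, 1], y = m[, 2], z = m[, 3], label = lbl)
  }
  tab <- rbind(
    as_rows(voxels$healthy_bone, "healthy_bone"),
    as_rows(voxels$intracortical_tumor, "intracortical_tumor"),
    as_rows(voxels$extraosseous_tumor, "extraosseous_tumor"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxels
#' @param pitch grid pitch of the stored model (mm).
#' @export
read_voxels <- function(path, pitch) {
  tab <- utils::read.csv(path)
  pick <- function(lbl) as.matrix(tab[tab$label == lbl, c("x", "y", "z")])
  structure(list(pitch = pitch, origin = NA_real_, origin_offset = c(0, 0, 0),
                 healthy_bone = pick("healthy_bone"),
                 intracortical_tumor = pick("intracortical_tumor"),
                 extraosseous_tumor = pick("extraosseous_tumor")),
            class = "voxel_model")
}
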