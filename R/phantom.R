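#' Phantom specification
#'
#' Parametric synthetic bone + tumor geometry with known analytic
#' properties, standing in for segmented knee cases. The bone is a
#' long-bone-like generalized cylinder along z: a tapered shaft whose
#' radius is modulated near the top end by a smooth condylar bulge with a
#' mild two-lobed angular profile. The tumor is a star-shaped radial solid
#' (sphere, ellipsoid, or a sphere perturbed by seed-controlled low-order
#' spherical harmonics for the lobed shape) placed so it overlaps the bone;
#' an off-axis placement past the cortical surface gives extraosseous
#' extension.
#'
#' @param shaft_radius bone shaft radius, mm.
#' @param shaft_length bone length, mm.
#' @param condyle_bulge relative bulge amplitude (0 = plain shaft).
#' @param taper relative radius loss from the condylar end to the far end.
#' @param tumor_shape `"sphere"`, `"ellipsoid"` or `"lobed"`.
#' @param tumor_radii length 1 (sphere/lobed base radius) or 3 (ellipsoid
#'   semi-axes), mm.
#' @param tumor_center tumor center offset from the bone axis midpoint, mm.
#' @param lobe_amplitude relative harmonic amplitude for `"lobed"` (< 0.3
#'   keeps the solid star-shaped about its center).
#' @param mesh_resolution icosphere subdivision level for the tumor and
#'   angular/axial density scale for the bone.
#' @param seed integer seed controlling the lobed-harmonic coefficients.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shaft_radius = 20, shaft_length = 120,
                         condyle_bulge = 0.35, taper = 0.15,
                         tumor_shape = c("sphere", "ellipsoid", "lobed"),
                         tumor_radii = 12, tumor_center = c(0, 0, 15),
                         lobe_amplitude = 0.15,
                         mesh_resolution = 2, seed = 1) {
  tumor_shape <- match.arg(tumor_shape)
  stopifnot(shaft_radius > 0, shaft_length > 0, condyle_bulge >= 0,
            taper >= 0, taper < 1, all(tumor_radii > 0),
            length(tumor_center) == 3, lobe_amplitude >= 0,
            lobe_amplitude < 0.3, mesh_resolution >= 1)
  if (tumor_shape == "ellipsoid" && length(tumor_radii) != 3) {
    stop("ellipsoid tumor needs 3 semi-axes")
  }
  structure(list(shaft_radius = shaft_radius, shaft_length = shaft_length,
                 condyle_bulge = condyle_bulge, taper = taper,
                 tumor_shape = tumor_shape, tumor_radii = tumor_radii,
                 tumor_center = tumor_center,
                 lobe_amplitude = lobe_amplitude,
                 mesh_resolution = as.integer(mesh_resolution),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# bone radius profile r(theta, z01), z01 in [0, 1] (1 = condylar end)
bone_radius_profile <- function(spec, theta, z01) {
  base <- spec$shaft_radius * (1 - spec$taper * (1 - z01))
  bulge <- exp(-((z01 - 0.88) / 0.10)^2)
  lobes <- 1 + 0.25 * cos(2 * theta)
  base * (1 + spec$condyle_bulge * bulge * lobes)
}

make_bone_mesh <- function(spec) {
  n_theta <- 8 * spec$mesh_resolution
  n_z <- 12 * spec$mesh_resolution + 1
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  z01 <- seq(0, 1, length.out = n_z)
  z <- (z01 - 0.5) * spec$shaft_length
  verts <- matrix(0, n_theta * n_z, 3)
  for (j in seq_len(n_z)) {
    r <- bone_radius_profile(spec, theta, z01[j])
    rows <- (j - 1) * n_theta + seq_len(n_theta)
    verts[rows, ] <- cbind(r * cos(theta), r * sin(theta), z[j])
  }
  # end cap centers
  bot <- c(0, 0, min(z))
  top <- c(0, 0, max(z))
  verts <- rbind(verts, bot, top)
  i_bot <- nrow(verts) - 1L
  i_top <- nrow(verts)
  idx <- function(i, j) (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  faces <- vector("list", n_z + 1)
  for (j in seq_len(n_z - 1)) {
    i <- seq_len(n_theta)
    a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i, j + 1); d <- idx(i + 1, j + 1)
    faces[[j]] <- rbind(cbind(a, b, d), cbind(a, d, cc))
  }
  i <- seq_len(n_theta)
  faces[[n_z]] <- cbind(i_bot, idx(i + 1, 1), idx(i, 1))
  faces[[n_z + 1]] <- cbind(i_top, idx(i, n_z), idx(i + 1, n_z))
  surface_mesh(verts, do.call(rbind, faces), label = "bone")
}

make_tumor_mesh <- function(spec) {
  sub <- spec$mesh_resolution
  radial <- switch(spec$tumor_shape,
    sphere = function(u) rep(spec$tumor_radii[1], nrow(u)),
    ellipsoid = function(u) {
      a <- spec$tumor_radii
      1 / sqrt((u[, 1] / a[1])^2 + (u[, 2] / a[2])^2 + (u[, 3] / a[3])^2)
    },
    lobed = {
      coef <- (function() {
        old <- if (exists(".Random.seed", globalenv()))
          get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(spec$seed)
        stats::runif(6, -1, 1)
      })()
      function(u) {
        # low-order real spherical-harmonic perturbation, star-shaped
        x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
        h <- coef[1] * x * y + coef[2] * y * z + coef[3] * x * z +
          coef[4] * (x^2 - y^2) + coef[5] * (3 * z^2 - 1) / 2 + coef[6] * z
        spec$tumor_radii[1] * (1 + spec$lobe_amplitude * h / 2)
      }
    })
  m <- radial_mesh(radial, center = spec$tumor_center, subdivisions = sub)
  m$label <- "tumor"
  m
}

#' Analytic tumor volume of a phantom
#'
#' Exact for spheres and ellipsoids; for lobed tumors the mesh volume is
#' reported (no closed form).
#'
#' @param spec a [phantom_spec()].
#' @return Volume in mm^3.
#' @export
phantom_tumor_volume <- function(spec) {
  switch(spec$tumor_shape,
    sphere = 4 / 3 * pi * spec$tumor_radii[1]^3,
    ellipsoid = 4 / 3 * pi * prod(spec$tumor_radii),
    lobed = mesh_volume(make_tumor_mesh(spec)))
}

#' Build a phantom scene
#'
#' Generates the watertight bone and tumor meshes for a [phantom_spec()],
#' voxelizes them, centers the scene on the tumor centroid and attaches
#' the analytic volumes.
#'
#' @param spec a [phantom_spec()].
#' @param pitch voxel grid pitch, mm.
#' @return A centered [scene()] with `sc$analytic` carrying the spec and
#'   analytic volumes.
#' @export
make_scene <- function(spec, pitch = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  bone <- make_bone_mesh(spec)
  tumor <- make_tumor_mesh(spec)
  sc <- tryCatch(scene(bone, tumor, pitch = pitch),
                 error = function(e) stop("invalid phantom spec: ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(sc$voxels$intracortical_tumor) == 0) {
    stop("invalid phantom spec: tumor does not intersect the bone")
  }
  sc <- center_on_tumor(sc)
  sc$analytic <- list(spec = spec,
                      tumor_volume = phantom_tumor_volume(spec),
                      bone_mesh_volume = mesh_volume(bone),
                      tumor_mesh_volume = mesh_volume(tumor))
  sc
}

#' Generate a stratified phantom suite
#'
#' Deterministically samples `n` phantom specs spanning tumor sizes
#' (small/medium/large relative to the shaft), centered and eccentric
#' placements (eccentric ones breach the cortex, giving extraosseous
#' extension), and the three tumor shapes.
#'
#' @param n number of phantoms (>= 1).
#' @param seed integer master seed.
#' @param shaft_radius,shaft_length bone dimensions shared by the suite, mm.
#' @return List of `n` [phantom_spec()] objects.
#' @export
make_suite <- function(n = 20, seed = 1, shaft_radius = 20,
                       shaft_length = 120) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sizes <- c(small = 0.4, medium = 0.55, large = 0.7)   # radius / shaft_radius
  shapes <- c("sphere", "ellipsoid", "lobed")
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    size <- sizes[[((i - 1) %% 3) + 1]] * shaft_radius *
      stats::runif(1, 0.9, 1.1)
    shape <- shapes[[((i - 1) %/% 3) %% 3 + 1]]
    eccentric <- i %% 2 == 0    # every second phantom breaches the cortex
    off_r <- if (eccentric) shaft_radius * stats::runif(1, 0.7, 0.95) else
      shaft_radius * stats::runif(1, 0, 0.2)
    ang <- stats::runif(1, 0, 2 * pi)
    cz <- stats::runif(1, 0.0, 0.3) * shaft_length
    radii <- switch(shape,
      sphere = size,
      ellipsoid = size * stats::runif(3, 0.75, 1.25),
      lobed = size)
    specs[[i]] <- phantom_spec(
      shaft_radius = shaft_radius, shaft_length = shaft_length,
      tumor_shape = shape, tumor_radii = radii,
      tumor_center = c(off_r * cos(ang), off_r * sin(ang), cz),
      lobe_amplitude = if (shape == "lobed") 0.15 else 0,
      seed = sample.int(1e6, 1))
  }
  specs
}

#' Write a phantom to disk
#'
#' Writes the bone and tumor meshes (STL) and a JSON sidecar with the spec
#' and analytic volumes. File names carry a `synthetic_` prefix: these are
#' generated stand-ins for segmented patient anatomy.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory.
#' @param ascii write ASCII STL.
#' @return Named character vector of written paths, invisibly.
#' @export
write_phantom <- function(spec, dir, ascii = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(bone = file.path(dir, "synthetic_bone.stl"),
             tumor = file.path(dir, "synthetic_tumor.stl"),
             spec = file.path(dir, "synthetic_phantom.json"))
  write_mesh(make_bone_mesh(spec), paths[["bone"]], ascii = ascii)
  write_mesh(make_tumor_mesh(spec), paths[["tumor"]], ascii = ascii)
  jsonlite::write_json(
    list(spec = unclass(spec), tumor_volume = phantom_tumor_volume(spec)),
    paths[["spec"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s tumor (r=%s mm) at (%g, %g, %g) in shaft r=%g mm\n",
              x$tumor_shape, paste(signif(x$tumor_radii, 3), collapse = "/"),
              x$tumor_center[1], x$tumor_center[2], x$tumor_center[3],
              x$shaft_radius))
  invisible(x)
}
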