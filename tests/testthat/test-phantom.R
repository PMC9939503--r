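test_that("phantom meshes are watertight, deterministic and analytically sized", {
  spec <- phantom_spec(tumor_shape = "lobed", tumor_radii = 11,
                       lobe_amplitude = 0.18, seed = 7)
  m1 <- resectplanr:::make_tumor_mesh(spec)
  m2 <- resectplanr:::make_tumor_mesh(spec)
  expect_identical(m1, m2)
  expect_silent(check_watertight(m1))
  expect_silent(check_watertight(resectplanr:::make_bone_mesh(spec)))
  expect_equal(euler_characteristic(m1), 2)
  # different harmonic seed, different shape
  m3 <- resectplanr:::make_tumor_mesh(
    phantom_spec(tumor_shape = "lobed", tumor_radii = 11,
                 lobe_amplitude = 0.18, seed = 8))
  expect_gt(max(abs(m1$vertices - m3$vertices)), 0.1)
})

test_that("a tumor contained in the shaft has no extraosseous voxels", {
  sc <- make_scene(phantom_spec(shaft_radius = 20, shaft_length = 100,
                                tumor_radii = 10, tumor_center = c(0, 0, 0),
                                mesh_resolution = 1), pitch = 2)
  expect_identical(nrow(sc$voxels$extraosseous_tumor), 0L)
  expect_gt(nrow(sc$voxels$intracortical_tumor), 0)
})

test_that("voxel counts track the analytic tumor volume within 5%", {
  for (spec in list(
    phantom_spec(tumor_radii = 10.5, tumor_center = c(0.4, -0.2, 0.3)),
    phantom_spec(tumor_shape = "ellipsoid", tumor_radii = c(12, 10, 14),
                 tumor_center = c(0.2, 0.3, -0.4)))) {
    sc <- make_scene(spec, pitch = 2)
    vox_vol <- sum(voxel_volumes(sc$voxels)[c("intracortical_tumor",
                                              "extraosseous_tumor")])
    expect_lt(abs(vox_vol - sc$analytic$tumor_volume) /
                sc$analytic$tumor_volume, 0.05)
  }
})

test_that("non-intersecting phantom solids are rejected", {
  expect_error(make_scene(phantom_spec(shaft_radius = 10, shaft_length = 60,
                                       tumor_radii = 5,
                                       tumor_center = c(40, 0, 0)),
                          pitch = 2),
               "invalid phantom spec")
})

test_that("the suite is deterministic, stratified and voxelizable", {
  suite <- make_suite(20, seed = 5)
  suite2 <- make_suite(20, seed = 5)
  expect_identical(suite, suite2)
  expect_length(suite, 20)
  shapes <- vapply(suite, `[[`, "", "tumor_shape")
  expect_setequal(unique(shapes), c("sphere", "ellipsoid", "lobed"))
  offsets <- vapply(suite, function(s) sqrt(sum(s$tumor_center[1:2]^2)), 0)
  expect_gt(max(offsets), 10)          # eccentric cases present
  expect_lt(min(offsets), 5)           # centered cases present
  # every second spec is eccentric by construction; check one breaches cortex
  ecc <- suite[[which.max(offsets)]]
  sc <- make_scene(ecc, pitch = 2)
  expect_gt(nrow(sc$voxels$extraosseous_tumor), 0)
  # a centered case voxelizes with intracortical volume too
  cen <- suite[[which.min(offsets)]]
  sc2 <- make_scene(cen, pitch = 2)
  expect_gt(nrow(sc2$voxels$intracortical_tumor), 0)
})

test_that("enlarging the tumor never shrinks the optimal conical waste volume", {
  # coarse deterministic parameter grid as the optimization oracle
  grid <- expand.grid(theta_z = c(0, 90), theta_y = c(0, 45, 90),
                      theta_x = c(0, 90), t_z = c(-200000, -100, -20))
  best_removed <- sapply(c(6, 8, 10), function(r) {
    sc <- make_scene(phantom_spec(shaft_radius = 14, shaft_length = 70,
                                  condyle_bulge = 0.2, tumor_radii = r,
                                  tumor_center = c(0.3, -0.2, 5.2),
                                  mesh_resolution = 1), pitch = 2)
    min(apply(grid, 1, function(g) {
      p <- rg_params(g[1], g[2], g[3], 0, 0, g[4], rg_type = "conical")
      evaluate_rg(sc, p)$removed_count * 8
    }))
  })
  expect_true(all(diff(best_removed) >= 0))
})

test_that("phantom files carry the synthetic label and analytic sidecar", {
  dir <- tempfile()
  paths <- write_phantom(phantom_spec(mesh_resolution = 1), dir)
  expect_true(all(file.exists(paths)))
  expect_true(all(grepl("synthetic_", basename(paths))))
  side <- jsonlite::read_json(paths[["spec"]])
  expect_equal(side$tumor_volume, 4 / 3 * pi * 12^3, tolerance = 1e-6)
  m <- load_mesh(paths[["bone"]], "bone")
  expect_silent(check_watertight(m))
})
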