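test_that("to_local realizes the translation convention and preserves distances", {
  sc <- fixture("tiny_scene")
  zmin <- min(sc$tumor_mesh$vertices[, 3])
  p <- rg_params(0, 0, 0, 0, 0, zmin, rg_type = "conical")
  loc <- to_local(sc, p)
  expect_equal(min(loc$tumor_vertices[, 3]), 0, tolerance = 1e-9)
  # rigid motion: pairwise distances preserved
  i <- c(1, 10, 25); j <- c(3, 17, 40)
  p2 <- rg_params(35, -60, 120, 2, -3, -50, rg_type = "conical")
  loc2 <- to_local(sc, p2)
  d0 <- sqrt(rowSums((sc$bone_mesh$vertices[i, ] - sc$tumor_mesh$vertices[j, ])^2))
  d2 <- sqrt(rowSums((loc2$bone_vertices[i, ] - loc2$tumor_vertices[j, ])^2))
  expect_equal(d0, d2, tolerance = 1e-9)
  # +180 and -180 degree z rotations coincide
  la <- to_local(sc, rg_params(180, 10, 20, 0, 0, -40, rg_type = "conical"))
  lb <- to_local(sc, rg_params(-180, 10, 20, 0, 0, -40, rg_type = "conical"))
  expect_equal(la$tumor_vertices, lb$tumor_vertices, tolerance = 1e-9)
})

test_that("bone waste implements the removed/(removed + intracortical) percentage", {
  expect_equal(bone_waste(0, 150), 0)
  expect_equal(bone_waste(50, 150), 25)
  expect_equal(bone_waste(150, 150), 50)
  expect_error(bone_waste(10, 0), "undefined")
})

test_that("every intracortical voxel is removed and the RGs nest, over random draws", {
  for (scene_name in c("tiny_scene", "eccentric_scene")) {
    sc <- fixture(scene_name)
    draws <- random_params(sc, "contoured", 12,
                           seed = if (scene_name == "tiny_scene") 31 else 32)
    for (p7 in draws) {
      p6 <- params_vector(p7)[1:6]
      ev_con <- evaluate_rg(sc, resectplanr:::vector_params(p6, "conical"),
                            with_masks = TRUE)
      ev_flat <- evaluate_rg(sc, resectplanr:::vector_params(p6, "flat"),
                             with_masks = TRUE)
      ev_cnt <- evaluate_rg(sc, p7, with_masks = TRUE)
      expect_true(all(ev_con$intracortical_mask))
      expect_true(all(ev_flat$intracortical_mask))
      expect_true(all(ev_cnt$intracortical_mask))
      expect_true(all(ev_flat$removed %in% ev_con$removed))
      expect_true(all(ev_cnt$removed %in% ev_flat$removed))
    }
  }
})

test_that("the flat facing cut spares exactly the bone below the tumor base", {
  # tumor resting on the lowest bone layer: flat and conical coincide
  bone <- box_mesh(c(0, 0, 0), c(40, 40, 40), label = "bone")
  tumor <- icosphere(2, radius = 10, center = c(20, 20, 10))
  tumor$vertices[, 3] <- pmax(tumor$vertices[, 3], 0)   # clip at bone floor
  tumor <- surface_mesh(tumor$vertices, tumor$faces, label = "tumor")
  sc <- center_on_tumor(scene(bone, tumor, pitch = 2))
  p <- rg_params(0, 0, 0, 0, 0, -300, rg_type = "conical")
  pf <- rg_params(0, 0, 0, 0, 0, -300, rg_type = "flat")
  ev_c <- evaluate_rg(sc, p)
  ev_f <- evaluate_rg(sc, pf)
  expect_setequal(ev_f$removed, ev_c$removed)
  # deep tumor: flat is strictly smaller
  sc2 <- fixture("tiny_scene")
  ev_c2 <- evaluate_rg(sc2, p)
  ev_f2 <- evaluate_rg(sc2, pf)
  expect_true(all(ev_f2$removed %in% ev_c2$removed))
  expect_lt(ev_f2$removed_count, ev_c2$removed_count)
})

test_that("a distant focal point on the axis carves the circumscribing cylinder", {
  bone <- cylinder_mesh(radius = 25, length = 100, n_theta = 32, label = "bone")
  # generic off-lattice sphere placement (see the voxelization tests)
  tumor <- icosphere(3, radius = 10, center = c(0.6, -0.3, 0.4))
  tumor$label <- "tumor"
  sc <- center_on_tumor(scene(bone, tumor, pitch = 2))
  p <- rg_params(0, 0, 0, 0, 0, -200000, rg_type = "conical")
  rg <- build_resection(sc, p)
  # analytic oracle: circumscribing cylinder clipped to the bone, minus sphere
  expected <- pi * 10^2 * 100 - 4 / 3 * pi * 10^3
  expect_lt(abs(rg$removed_volume - expected) / expected, 0.10)
  # and the waste respects its bounds
  expect_gt(rg$waste$bone_waste_pct, 0)
  expect_lt(rg$waste$bone_waste_pct, 100)
})

test_that("removal masks match the brute-force LP oracle (no hull shortcuts)", {
  sc <- fixture("tiny_scene")
  draws <- random_params(sc, "contoured", 2, seed = 55)
  for (p7 in draws) {
    for (tp in c("conical", "flat", "contoured")) {
      p <- if (tp == "contoured") p7 else
        resectplanr:::vector_params(params_vector(p7)[1:6], tp)
      ev <- evaluate_rg(sc, p)
      loc <- to_local(sc, p)
      hull_pts <- loc$tumor_vertices[
        convex_hull_3d(loc$tumor_vertices)$vertices, , drop = FALSE]
      # subsample voxels for the per-point LP
      set.seed(99)
      idx <- sample(nrow(loc$healthy_bone), 250)
      B <- loc$healthy_bone[idx, , drop = FALSE]
      oracle <- unname(lp_in_cone(B, hull_pts)) & B[, 3] >= -1e-9
      if (tp == "flat") {
        oracle <- oracle & B[, 3] > min(loc$tumor_vertices[, 3]) - 1e-9
      }
      if (tp == "contoured") {
        oracle <- oracle & unname(lp_in_hull(B[, c(1, 3), drop = FALSE],
                                             hull_pts[, c(1, 3)]))
      }
      expect_identical(idx %in% ev$removed, oracle)
    }
  }
})

test_that("profile extension clears all removed bone and never changes counts", {
  sc <- fixture("small_scene")
  p <- rg_params(20, -30, 45, 1, -2, -80, rg_type = "conical")
  rg0 <- build_resection(sc, p, extend = FALSE)
  rg <- extend_profile(rg0, sc, clearance = 5)
  expect_identical(rg$removed_indices, rg0$removed_indices)
  expect_identical(rg$waste$bone_waste_pct, rg0$waste$bone_waste_pct)
  # every removed voxel is closer to the focal point than the extended loop
  tf <- function(pts) sweep(pts %*% t(rg$local$M), 2, rg$local$tq)
  B <- tf(sc$voxels$healthy_bone[rg$removed_indices, , drop = FALSE])
  ext_local <- tf(rg$profile_3d$extended)
  expect_lt(sqrt(max(rowSums(B^2))),
            min(sqrt(rowSums(ext_local^2))) + 1e-6)
  # re-extending an already-clear profile leaves the reach unchanged
  rg2 <- extend_profile(rg, sc, clearance = 5)
  expect_equal(rg2$extension$reach, rg$extension$reach)
})

test_that("the planar baseline counts half-space voxels and rejects cutting the tumor", {
  sc <- fixture("tiny_scene")
  zs <- sc$voxels$intracortical_tumor[, 3]
  offset <- min(zs) - 3
  w <- planar_baseline(sc, c(0, 0, 1), offset)
  expect_equal(w$removed_count, sum(sc$voxels$healthy_bone[, 3] >= offset))
  expect_equal(w$bone_waste_pct,
               bone_waste(w$removed_count, nrow(sc$voxels$intracortical_tumor)))
  expect_error(planar_baseline(sc, c(0, 0, 1), mean(zs)), "infeasible")
})

test_that("waste counts are invariant under a lattice rotation of the whole scene", {
  sc <- fixture("tiny_scene")
  Q <- resectplanr:::rot_z(90)
  rotate <- function(m) m %*% t(Q)
  bone2 <- surface_mesh(rotate(sc$bone_mesh$vertices), sc$bone_mesh$faces,
                        label = "bone")
  tumor2 <- surface_mesh(rotate(sc$tumor_mesh$vertices), sc$tumor_mesh$faces,
                         label = "tumor")
  vx2 <- sc$voxels
  for (nm in c("healthy_bone", "intracortical_tumor", "extraosseous_tumor")) {
    if (nrow(vx2[[nm]])) vx2[[nm]] <- rotate(vx2[[nm]])
  }
  sc2 <- scene(bone2, tumor2, voxels = vx2)
  sc2$centered <- TRUE
  for (ang in c(-40, 10, 77)) {
    p1 <- rg_params(ang + 90, 15, -25, 1, 2, -60, rg_type = "conical")
    p2 <- rg_params(ang, 15, -25, 1, 2, -60, rg_type = "conical")
    ev1 <- evaluate_rg(sc, p1)     # extra +90 z rotation on the base scene
    ev2 <- evaluate_rg(sc2, p2)    # scene itself pre-rotated by 90
    expect_equal(ev1$removed_count, ev2$removed_count)
  }
})
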