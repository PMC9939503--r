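tiny_cfg <- function(seed = 42) {
  swarm_config(n_particles = 10, n_restarts = 2, seed = seed,
               max_iter_per_param = 15)
}

test_that("run_plan produces an internally consistent, verifiable report", {
  spec <- phantom_spec(shaft_radius = 14, shaft_length = 70, tumor_radii = 8,
                       tumor_center = c(0.3, 0.1, 6), mesh_resolution = 1)
  out <- tempfile()
  rep <- run_plan(spec = spec, config = tiny_cfg(), out_dir = out)
  w <- rep$comparison$bone_waste_pct
  expect_equal(rep$improvements$conical_to_flat, w[1] - w[2])
  expect_equal(rep$improvements$flat_to_contoured, w[2] - w[3])
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "log.jsonl")))
  expect_true(file.exists(file.path(out, "voxels.csv.gz")))
  expect_true(file.exists(file.path(out, "conical_cut_surface.ply")))
  # the verify subcommand's core: every stored waste re-counts identically
  expect_true(verify_report(out))
  # log lines parse and carry the seed
  logs <- lapply(readLines(file.path(out, "log.jsonl")), jsonlite::fromJSON)
  expect_true(all(vapply(logs, function(l) l$seed == 42, TRUE)))
})

test_that("a rerun from the logged seed and config reproduces the report", {
  spec <- phantom_spec(shaft_radius = 14, shaft_length = 70, tumor_radii = 8,
                       tumor_center = c(0.3, 0.1, 6), mesh_resolution = 1)
  out <- tempfile()
  rep1 <- run_plan(spec = spec, config = tiny_cfg(9), out_dir = out)
  stored <- read_report(out)
  cfg2 <- do.call(swarm_config, stored$config)
  spec2 <- do.call(phantom_spec, stored$provenance$spec)
  rep2 <- run_plan(spec = spec2, pitch = stored$provenance$pitch,
                   margin_scale = stored$provenance$margin_scale,
                   config = cfg2)
  for (tp in names(rep1$results)) {
    expect_identical(rep1$results[[tp]]$best_waste_pct,
                     rep2$results[[tp]]$best_waste_pct)
    expect_identical(rep1$results[[tp]]$per_restart_best,
                     rep2$results[[tp]]$per_restart_best)
    expect_identical(params_vector(rep1$results[[tp]]$best_params),
                     params_vector(rep2$results[[tp]]$best_params))
  }
})

test_that("unit margin scaling is the identity on the whole pipeline", {
  spec <- phantom_spec(shaft_radius = 12, shaft_length = 60, tumor_radii = 7,
                       tumor_center = c(0.2, 0, 5), mesh_resolution = 1)
  cfg <- swarm_config(n_particles = 8, n_restarts = 1, seed = 4,
                      max_iter_per_param = 10)
  r1 <- run_plan(spec = spec, config = cfg, rg_types = "conical")
  r2 <- run_plan(spec = spec, config = cfg, rg_types = "conical",
                 margin_scale = 1)
  expect_identical(r1$results$conical$best_waste_pct,
                   r2$results$conical$best_waste_pct)
  # margin > 1 grows the resection target
  r3 <- run_plan(spec = spec, config = cfg, rg_types = "conical",
                 margin_scale = 1.2)
  expect_gt(r3$voxel_volumes[["intracortical_tumor"]],
            r1$voxel_volumes[["intracortical_tumor"]])
})

test_that("the planar baseline comparison reports percentage-point improvements", {
  spec <- phantom_spec(shaft_radius = 14, shaft_length = 70, tumor_radii = 8,
                       tumor_center = c(0.3, 0.1, 6), mesh_resolution = 1)
  rep <- run_plan(spec = spec, config = tiny_cfg())
  rep <- compare_baseline(rep)
  expect_true(rep$baseline$feasible)
  bw <- rep$baseline$waste$bone_waste_pct
  for (tp in names(rep$results)) {
    expect_equal(rep$baseline_improvements[[tp]]$percentage_points,
                 bw - rep$results[[tp]]$best_waste_pct)
  }
  # deep-seated tumor: every hull-type geometry beats the best plane
  expect_true(all(vapply(rep$baseline_improvements,
                         function(i) i$percentage_points > 0, TRUE)))
})

test_that("errors surface with the failing stage named", {
  expect_error(run_plan(bone_path = "no_such.stl", tumor_path = "no.stl",
                        config = tiny_cfg()),
               "stage 'load'")
})
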