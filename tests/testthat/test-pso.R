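test_that("the swarm solves the 6-D sphere function and bookkeeps correctly", {
  cfg <- swarm_config(n_restarts = 2, seed = 101)
  res <- pso_minimize(function(x) sum(x^2), rep(-5, 6), rep(5, 6), cfg)
  expect_lt(res$best_value, 1e-3)
  expect_equal(res$best_value, min(res$per_restart_best))
  for (tr in res$trace) expect_true(all(diff(tr) <= 0))
  expect_true(all(res$iterations <= 200 * 6))
})

test_that("a fixed seed reproduces bit-identical optimization results", {
  cfg <- swarm_config(n_particles = 15, n_restarts = 2, seed = 7,
                      max_iter_per_param = 20)
  f <- function(x) sum((x - 1)^2) + 0.1 * sum(sin(3 * x)^2)
  r1 <- pso_minimize(f, rep(-4, 4), rep(4, 4), cfg)
  r2 <- pso_minimize(f, rep(-4, 4), rep(4, 4), cfg)
  expect_identical(r1, r2)
})

test_that("every evaluated position respects the box bounds", {
  lower <- c(-2, 0, 10); upper <- c(2, 5, 12)
  seen <- list()
  f <- function(x) { seen[[length(seen) + 1]] <<- x; sum(x^2) }
  cfg <- swarm_config(n_particles = 10, n_restarts = 2, seed = 3,
                      max_iter_per_param = 15, cache = FALSE)
  pso_minimize(f, lower, upper, cfg)
  M <- do.call(rbind, seen)
  expect_true(all(sweep(M, 2, lower, `>=`)))
  expect_true(all(sweep(M, 2, upper, `<=`)))
})

test_that("the reported optimum is invariant to restart order", {
  f <- function(x) sum(x^2) + cos(5 * x[1])
  cfg <- swarm_config(n_particles = 12, n_restarts = 4, seed = 11,
                      max_iter_per_param = 15)
  seeds <- resectplanr:::derive_subseeds(11, 4)
  r1 <- pso_minimize(f, rep(-3, 3), rep(3, 3), cfg, sub_seeds = seeds)
  r2 <- pso_minimize(f, rep(-3, 3), rep(3, 3), cfg, sub_seeds = rev(seeds))
  expect_equal(r1$best_value, r2$best_value)
})

test_that("a constant objective triggers the stall-based early termination", {
  cfg <- swarm_config(n_particles = 5, n_restarts = 1, seed = 2)
  res <- pso_minimize(function(x) 1, c(-1, -1), c(1, 1), cfg)
  expect_identical(res$iterations, cfg$stall_limit)
})

test_that("failed objective evaluations score +Inf and the search continues", {
  f <- function(x) if (x[1] > 0) stop("boom") else sum(x^2)
  cfg <- swarm_config(n_particles = 10, n_restarts = 1, seed = 5,
                      max_iter_per_param = 20)
  res <- pso_minimize(f, c(-2, -2), c(2, 2), cfg)
  expect_true(is.finite(res$best_value))
  expect_lte(res$best_par[1], 0)
})

test_that("resection bounds have the table dimensions and tumor-extent limits", {
  sc <- fixture("tiny_scene")
  b6 <- bounds_for("conical", sc)
  b7 <- bounds_for("contoured", sc)
  expect_length(b6$lower, 6)
  expect_length(b7$lower, 7)
  expect_equal(b7$lower[7], -90)
  expect_equal(b7$upper[7], 90)
  expect_equal(b6$lower[6], -200000)
  # centered ~spherical tumor: t_x static bound ~ its circumscribing radius
  rmax <- sqrt(max(rowSums(sc$tumor_hull$verts^2)))
  expect_equal(b6$upper[4], rmax)
  # at evaluation time t_z is clamped to the rotated tumor minimum
  p <- rg_params(0, 0, 0, 0, 0, 0, rg_type = "conical")
  loc <- to_local(sc, p)
  expect_equal(loc$translation[3], min(sc$tumor_hull$verts[, 3]))
})

test_that("optimizing a scene returns in-bounds parameters matching their waste", {
  sc <- fixture("tiny_scene")
  cfg <- swarm_config(n_particles = 12, n_restarts = 2, seed = 19,
                      max_iter_per_param = 25)
  opt <- optimize_resection(sc, "flat", cfg)
  b <- bounds_for("flat", sc)
  v <- params_vector(opt$best_params)
  expect_true(all(v >= b$lower & v <= b$upper))
  ev <- evaluate_rg(sc, opt$best_params)
  expect_equal(bone_waste(ev$removed_count, ev$intracortical_count),
               opt$best_waste_pct)
  # memoization does not alter the result
  cfg_nc <- swarm_config(n_particles = 12, n_restarts = 2, seed = 19,
                         max_iter_per_param = 25, cache = FALSE)
  opt_nc <- optimize_resection(sc, "flat", cfg_nc)
  expect_equal(opt_nc$best_waste_pct, opt$best_waste_pct)
})

test_that("a contoured optimum re-evaluated without its facing cut cannot improve", {
  sc <- fixture("tiny_scene")
  cfg <- swarm_config(n_particles = 15, n_restarts = 2, seed = 23,
                      max_iter_per_param = 40)
  opt <- optimize_all(sc, cfg)
  expect_equal(opt$improvements$flat_to_contoured,
               opt$comparison$bone_waste_pct[2] - opt$comparison$bone_waste_pct[3])
  pc <- opt$results$contoured$best_params
  as_flat <- rg_params(pc$theta_z, pc$theta_y, pc$theta_x,
                       pc$t_x, pc$t_y, pc$t_z, rg_type = "flat")
  ev_flat <- evaluate_rg(sc, as_flat)
  w_flat <- bone_waste(ev_flat$removed_count, ev_flat$intracortical_count)
  expect_gte(w_flat + 1e-9, opt$results$contoured$best_waste_pct)
  # traces are capped at 200 iterations per parameter
  expect_lte(length(opt$results$contoured$trace[[1]]), 200 * 7 + 1)
})
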