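#' Swarm configuration
#'
#' Defaults: 50 particles, personal and
#' global learning coefficients 1.49, per-particle inertia initialized
#' uniformly in `[0.1, 1.1]` and adapted within that range, a maximum of
#' `200 * n_params` iterations, early termination after 20 iterations
#' without improvement of the global best, and 10 independent restarts.
#'
#' @param n_particles swarm size.
#' @param c_personal,c_global learning coefficients.
#' @param inertia_range inertia bounds (length 2, inside (0, 2)).
#' @param max_iter_per_param iteration cap multiplier: `max_iter =
#'   max_iter_per_param * n_params`.
#' @param stall_limit consecutive non-improving iterations before stopping.
#' @param n_restarts independent swarm restarts.
#' @param seed master RNG seed (integer); restart sub-seeds derive from it.
#' @param cache memoize objective values on parameter vectors quantized to
#'   1e-6 (saves repeated hull builds once the swarm contracts).
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 50, c_personal = 1.49,
                         c_global = 1.49, inertia_range = c(0.1, 1.1),
                         max_iter_per_param = 200, stall_limit = 20,
                         n_restarts = 10, seed = 1, cache = TRUE) {
  stopifnot(n_particles >= 2, c_personal > 0, c_global > 0,
            length(inertia_range) == 2, inertia_range[1] > 0,
            inertia_range[2] < 2, inertia_range[1] < inertia_range[2],
            max_iter_per_param > 0, stall_limit >= 1, n_restarts >= 1)
  structure(list(n_particles = as.integer(n_particles),
                 c_personal = c_personal, c_global = c_global,
                 inertia_range = inertia_range,
                 max_iter_per_param = max_iter_per_param,
                 stall_limit = as.integer(stall_limit),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), cache = isTRUE(cache)),
            class = "swarm_config")
}

derive_subseeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Bounded particle swarm minimization with restarts
#'
#' Minimizes `fn` over a box. Each restart runs an independent swarm from
#' its own sub-seed: uniform initialization in the box, velocity update
#' `v <- w v + c1 r1 (p - x) + c2 r2 (g - x)`, positions clamped to the
#' box with the violating velocity component zeroed, and per-particle
#' inertia adapted within `inertia_range` (increased 1.25x after an
#' iteration that improves the global best, decreased 0.75x after two
#' consecutive stalled iterations). A restart stops at `max_iter` or after
#' `stall_limit` iterations without relative improvement of the global
#' best beyond 1e-12. Failed objective evaluations score `+Inf` and the
#' search continues.
#'
#' @param fn objective: numeric vector -> scalar cost.
#' @param lower,upper box bounds (equal length).
#' @param config a [swarm_config()].
#' @param sub_seeds optional explicit restart seeds (overrides derivation
#'   from `config$seed`); the reported optimum is invariant to their order.
#' @return An object of class `pso_result`: `best_par`, `best_value`,
#'   `per_restart_best`, `per_restart_par`, `trace` (list of best-so-far
#'   vectors, one per restart, non-increasing), `evaluations`, `seed`,
#'   `sub_seeds`.
#' @export
pso_minimize <- function(fn, lower, upper, config = swarm_config(),
                         sub_seeds = NULL) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  d <- length(lower)
  if (is.null(sub_seeds)) sub_seeds <- derive_subseeds(config$seed, config$n_restarts)
  stopifnot(length(sub_seeds) == config$n_restarts)
  max_iter <- ceiling(config$max_iter_per_param * d)
  cache_env <- if (config$cache) new.env(parent = emptyenv()) else NULL
  n_eval <- 0L
  eval_fn <- function(x) {
    key <- if (!is.null(cache_env)) paste(round(x / 1e-6), collapse = ",") else NULL
    if (!is.null(key)) {
      hit <- cache_env[[key]]
      if (!is.null(hit)) return(hit)
    }
    n_eval <<- n_eval + 1L
    val <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(val)) val <- Inf
    if (!is.null(key) && length(cache_env) < 50000) cache_env[[key]] <- val
    val
  }
  restarts <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    set.seed(sub_seeds[r])
    span <- upper - lower
    X <- matrix(stats::runif(config$n_particles * d), ncol = d)
    X <- sweep(sweep(X, 2, span, `*`), 2, lower, `+`)
    V <- matrix(stats::runif(config$n_particles * d, -1, 1), ncol = d)
    V <- sweep(V, 2, span / 2, `*`)
    w <- stats::runif(config$n_particles, config$inertia_range[1],
                      config$inertia_range[2])
    cost <- apply(X, 1, eval_fn)
    P <- X
    pbest <- cost
    gi <- which.min(pbest)
    gbest <- pbest[gi]
    G <- P[gi, ]
    trace <- gbest
    stall <- 0L
    iter <- 0L
    while (iter < max_iter && stall < config$stall_limit) {
      iter <- iter + 1L
      r1 <- matrix(stats::runif(config$n_particles * d), ncol = d)
      r2 <- matrix(stats::runif(config$n_particles * d), ncol = d)
      V <- V * w + config$c_personal * r1 * (P - X) +
        config$c_global * r2 * (sweep(-X, 2, G, `+`))
      X <- X + V
      below <- sweep(X, 2, lower, `<`)
      above <- sweep(X, 2, upper, `>`)
      if (any(below)) {
        X[below] <- matrix(lower, config$n_particles, d, byrow = TRUE)[below]
        V[below] <- 0
      }
      if (any(above)) {
        X[above] <- matrix(upper, config$n_particles, d, byrow = TRUE)[above]
        V[above] <- 0
      }
      cost <- apply(X, 1, eval_fn)
      better <- cost < pbest
      pbest[better] <- cost[better]
      P[better, ] <- X[better, , drop = FALSE]
      gi <- which.min(pbest)
      improved <- pbest[gi] < gbest - 1e-12 * max(1, abs(gbest))
      if (pbest[gi] < gbest) {
        gbest <- pbest[gi]
        G <- P[gi, ]
      }
      if (improved) {
        stall <- 0L
        w <- pmin(w * 1.25, config$inertia_range[2])
      } else {
        stall <- stall + 1L
        if (stall >= 2L) w <- pmax(w * 0.75, config$inertia_range[1])
      }
      trace <- c(trace, gbest)
    }
    restarts[[r]] <- list(par = G, value = gbest, trace = trace,
                          iterations = iter, seed = sub_seeds[r])
  }
  values <- vapply(restarts, `[[`, 0, "value")
  best <- which.min(values)
  structure(list(best_par = restarts[[best]]$par,
                 best_value = values[best],
                 per_restart_best = values,
                 per_restart_par = lapply(restarts, `[[`, "par"),
                 trace = lapply(restarts, `[[`, "trace"),
                 iterations = vapply(restarts, `[[`, 0L, "iterations"),
                 evaluations = n_eval,
                 seed = config$seed, sub_seeds = sub_seeds),
            class = "pso_result")
}

#' Parameter box for a resection type
#'
#' The static optimization box. Rotations span +/-180 degrees; the
#' nominal translation bounds are rotation-dependent (rotated tumor
#' extents), so the static box uses the tumor's
#' circumscribing radius about the origin for `t_x`/`t_y`, `[-200000, 0]`
#' for `t_z`, and +/-90 degrees for `phi_z` (contoured). Evaluations clamp
#' the translation to the exact rotated extents (see [rg_params()]).
#'
#' @param rg_type `"conical"`, `"flat"` or `"contoured"`.
#' @param sc a centered [scene()].
#' @return List with `lower` and `upper` numeric vectors (length 6 or 7).
#' @export
bounds_for <- function(rg_type = c("conical", "flat", "contoured"), sc) {
  rg_type <- match.arg(rg_type)
  stopifnot(inherits(sc, "scene"))
  rmax <- sqrt(max(rowSums(sc$tumor_hull$verts^2)))
  if (rmax <= 0) stop("degenerate tumor: zero extent")
  lower <- c(-180, -180, -180, -rmax, -rmax, -200000)
  upper <- c(180, 180, 180, rmax, rmax, 0)
  if (rg_type == "contoured") {
    lower <- c(lower, -90)
    upper <- c(upper, 90)
  }
  list(lower = lower, upper = upper)
}

#' Optimize one resection geometry
#'
#' Minimizes bone waste over the parameter box of the given resection type
#' with [pso_minimize()].
#'
#' @param sc a centered [scene()].
#' @param rg_type `"conical"`, `"flat"` or `"contoured"`.
#' @param config a [swarm_config()].
#' @param warm_start optional [rg_params()] (e.g. a conical optimum)
#'   evaluated as an extra candidate and kept if it beats the swarm
#'   optimum; off by default since it can bias the flat/contoured result
#'   toward the conical basin.
#' @return An object of class `rg_optimization`: the `pso_result` fields
#'   plus `best_params` (an [rg_params()]), `best_waste_pct`, `rg_type`,
#'   and the realized `resection` ([build_resection()] at the optimum).
#' @export
optimize_resection <- function(sc, rg_type = c("conical", "flat", "contoured"),
                               config = swarm_config(), warm_start = NULL) {
  rg_type <- match.arg(rg_type)
  b <- bounds_for(rg_type, sc)
  fn <- function(x) {
    p <- vector_params(x, rg_type)
    ev <- evaluate_rg(sc, p)
    bone_waste(ev$removed_count, ev$intracortical_count)
  }
  res <- pso_minimize(fn, b$lower, b$upper, config)
  if (!is.null(warm_start)) {
    ws <- params_vector(warm_start)
    if (length(ws) < length(b$lower)) ws <- c(ws, 0)
    ws <- pmin(pmax(ws[seq_along(b$lower)], b$lower), b$upper)
    wv <- fn(ws)
    if (wv < res$best_value) {
      res$best_par <- ws
      res$best_value <- wv
    }
  }
  best_params <- vector_params(res$best_par, rg_type)
  out <- c(unclass(res),
           list(rg_type = rg_type,
                best_params = best_params,
                best_waste_pct = res$best_value,
                resection = build_resection(sc, best_params)))
  class(out) <- "rg_optimization"
  out
}

#' Optimize all three resection geometries
#'
#' Runs the conical, flat-based and contoured optimizations on one scene
#' and reports their wastes and pairwise percentage-point improvements.
#'
#' @param sc a centered [scene()].
#' @param config a [swarm_config()].
#' @param rg_types which geometries to run.
#' @return List with per-type `rg_optimization` results and a `comparison`
#'   data frame (waste per type and pairwise improvements).
#' @export
optimize_all <- function(sc, config = swarm_config(),
                         rg_types = c("conical", "flat", "contoured")) {
  results <- lapply(rg_types, function(tp) optimize_resection(sc, tp, config))
  names(results) <- rg_types
  waste <- vapply(results, `[[`, 0, "best_waste_pct")
  comparison <- data.frame(rg_type = rg_types, bone_waste_pct = waste,
                           row.names = NULL)
  improvements <- list()
  if (all(c("conical", "flat") %in% rg_types)) {
    improvements$conical_to_flat <- waste[["conical"]] - waste[["flat"]]
  }
  if (all(c("conical", "contoured") %in% rg_types)) {
    improvements$conical_to_contoured <- waste[["conical"]] - waste[["contoured"]]
  }
  if (all(c("flat", "contoured") %in% rg_types)) {
    improvements$flat_to_contoured <- waste[["flat"]] - waste[["contoured"]]
  }
  list(results = results, comparison = comparison,
       improvements = improvements)
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("pso_result: best %.6g after %d evaluations over %d restart(s)\n",
              x$best_value, x$evaluations, length(x$per_restart_best)))
  invisible(x)
}

#' @export
print.rg_optimization <- function(x, ...) {
  cat(sprintf("%s hull optimization: best bone waste %.2f%% (%d evaluations)\n",
              x$rg_type, x$best_waste_pct, x$evaluations))
  invisible(x)
}
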