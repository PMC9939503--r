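#' End-to-end resection planning run
#'
#' Executes the full pipeline: load (or generate) the bone and tumor
#' meshes, optionally apply a uniform margin expansion to the tumor,
#' voxelize, center on the tumor centroid, optimize the requested
#' resection geometries, and write a reproducible report (JSON), the
#' exported cut surfaces, the voxel model and a structured JSON-lines log
#' to `out_dir`.
#'
#' @param bone_path,tumor_path mesh files (STL/PLY, mm), or `NULL` when
#'   `spec` is given.
#' @param spec a [phantom_spec()] used instead of mesh files.
#' @param rg_types resection geometries to optimize.
#' @param pitch voxel pitch, mm.
#' @param margin_scale uniform tumor margin expansion factor (>= 1).
#' @param config a [swarm_config()]; its seed makes the run reproducible.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return An object of class `run_report`: scene provenance, per-RG
#'   optimization results, a comparison table, pairwise improvements
#'   (percentage points of bone waste), runtime metadata, and the scene.
#' @export
run_plan <- function(bone_path = NULL, tumor_path = NULL, spec = NULL,
                     rg_types = c("conical", "flat", "contoured"),
                     pitch = 2, margin_scale = 1,
                     config = swarm_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character()
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage, seed = config$seed), list(...))
    log_lines <<- c(log_lines, jsonlite::toJSON(rec, auto_unbox = TRUE))
  }
  stage <- "load"
  report <- tryCatch({
    if (!is.null(spec)) {
      provenance <- list(kind = "phantom", spec = unclass(spec),
                         pitch = pitch, margin_scale = margin_scale)
      bone <- make_bone_mesh(spec)
      tumor <- make_tumor_mesh(spec)
    } else {
      provenance <- list(kind = "files", bone_path = bone_path,
                         tumor_path = tumor_path, pitch = pitch,
                         margin_scale = margin_scale)
      bone <- load_mesh(bone_path, "bone")
      tumor <- load_mesh(tumor_path, "tumor")
    }
    log_stage("load", bone_faces = nrow(bone$faces),
              tumor_faces = nrow(tumor$faces))
    stage <- "margin"
    tumor_original <- tumor
    if (margin_scale > 1) tumor <- expand_margin(tumor, margin_scale)
    stage <- "voxelize"
    sc <- scene(bone, tumor, pitch = pitch)
    sc <- center_on_tumor(sc)
    if (!is.null(spec)) {
      sc$analytic <- list(spec = spec,
                          tumor_volume = phantom_tumor_volume(spec))
    }
    vols <- voxel_volumes(sc$voxels)
    log_stage("voxelize", healthy = unname(vols[1] / pitch^3),
              intracortical = unname(vols[2] / pitch^3),
              extraosseous = unname(vols[3] / pitch^3))
    stage <- "optimize"
    opt <- optimize_all(sc, config, rg_types = rg_types)
    for (tp in rg_types) {
      log_stage("optimize", rg_type = tp,
                best_waste_pct = opt$results[[tp]]$best_waste_pct,
                evaluations = opt$results[[tp]]$evaluations)
    }
    structure(list(provenance = provenance, rg_types = rg_types,
                   results = opt$results, comparison = opt$comparison,
                   improvements = opt$improvements,
                   voxel_volumes = vols,
                   config = unclass(config),
                   tumor_original_volume = mesh_volume(tumor_original),
                   runtime_s = proc.time()[["elapsed"]] - t0,
                   scene = sc, log = log_lines),
              class = "run_report")
  }, error = function(e) {
    stop(sprintf("run_plan failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Add the planar baseline comparison to a report
#'
#' Grid-searches the best single-plane resection and records, per
#' geometry, the improvement as the percentage-point difference in bone
#' waste (primary metric) and the relative percent reduction.
#'
#' @param report a [run_plan()] report.
#' @param subdivisions normal-grid density for [best_planar_baseline()].
#' @return The augmented report (`$baseline`, `$baseline_improvements`).
#' @export
compare_baseline <- function(report, subdivisions = 1) {
  stopifnot(inherits(report, "run_report"))
  base <- best_planar_baseline(report$scene, subdivisions = subdivisions)
  if (is.null(base)) {
    report$baseline <- list(feasible = FALSE)
    return(report)
  }
  bw <- base$waste$bone_waste_pct
  imps <- lapply(report$results, function(r) {
    list(percentage_points = bw - r$best_waste_pct,
         relative_pct = 100 * (bw - r$best_waste_pct) / bw)
  })
  report$baseline <- list(feasible = TRUE, waste = base$waste,
                          normal = base$normal, offset = base$offset)
  report$baseline_improvements <- imps
  report
}

#' Write / read a run report
#'
#' `write_report()` writes `report.json` (results, config, provenance,
#' improvements), `log.jsonl`, the voxel model (`voxels.csv.gz`) and the
#' exported cut surfaces into `dir`. `read_report()` reads the JSON back.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return The directory (write) or a list (read), invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  results_json <- lapply(report$results, function(r) {
    list(rg_type = r$rg_type,
         best_params = params_vector(r$best_params),
         best_waste_pct = r$best_waste_pct,
         best_waste_pct_whole_tumor =
           r$resection$waste$bone_waste_pct_whole_tumor,
         removed_count = r$resection$waste$removed_count,
         removed_volume = r$resection$removed_volume,
         per_restart_best = r$per_restart_best,
         iterations = r$iterations,
         evaluations = r$evaluations,
         sub_seeds = r$sub_seeds)
  })
  payload <- list(provenance = report$provenance,
                  config = report$config,
                  results = results_json,
                  improvements = report$improvements,
                  baseline = report$baseline,
                  baseline_improvements = report$baseline_improvements,
                  voxel_volumes = as.list(report$voxel_volumes),
                  runtime_s = report$runtime_s)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report$log, file.path(dir, "log.jsonl"))
  write_voxels(report$scene$voxels, file.path(dir, "voxels.csv.gz"))
  for (tp in names(report$results)) {
    export_resection(report$results[[tp]]$resection, dir, prefix = tp)
  }
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}

#' Re-verify a written report
#'
#' Independently re-counts every bone-waste number in a written report:
#' the scene is rebuilt from the stored provenance (phantom spec or mesh
#' paths plus pitch and margin), each stored optimal parameter vector is
#' re-evaluated, and the recomputed waste and removed-voxel counts are
#' compared with the stored values.
#'
#' @param dir directory written by [write_report()].
#' @param tol allowed absolute waste discrepancy (percentage points).
#' @return `TRUE` invisibly on success; error describing the first
#'   mismatch otherwise.
#' @export
verify_report <- function(dir, tol = 1e-9) {
  rep <- read_report(dir)
  prov <- rep$provenance
  if (identical(prov$kind, "phantom")) {
    spec <- do.call(phantom_spec, prov$spec[setdiff(names(prov$spec), NULL)])
    bone <- make_bone_mesh(spec)
    tumor <- make_tumor_mesh(spec)
  } else {
    bone <- load_mesh(prov$bone_path, "bone")
    tumor <- load_mesh(prov$tumor_path, "tumor")
  }
  if (prov$margin_scale > 1) tumor <- expand_margin(tumor, prov$margin_scale)
  sc <- center_on_tumor(scene(bone, tumor, pitch = prov$pitch))
  for (tp in names(rep$results)) {
    r <- rep$results[[tp]]
    params <- vector_params(as.numeric(r$best_params), r$rg_type)
    ev <- evaluate_rg(sc, params)
    w <- bone_waste(ev$removed_count, ev$intracortical_count)
    if (abs(w - r$best_waste_pct) > tol ||
        ev$removed_count != r$removed_count) {
      stop(sprintf(
        "verification failed for %s: stored %.6f%% (%d voxels), recomputed %.6f%% (%d voxels)",
        tp, r$best_waste_pct, r$removed_count, w, ev$removed_count))
    }
  }
  invisible(TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", x$provenance$kind, "scene\n")
  print(x$comparison)
  if (!is.null(x$baseline) && isTRUE(x$baseline$feasible)) {
    cat(sprintf("best planar baseline: %.2f%% waste\n",
                x$baseline$waste$bone_waste_pct))
  }
  invisible(x)
}
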