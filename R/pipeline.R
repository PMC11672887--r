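# End-to-end pipeline: phantom -> mesh -> plans -> simulation -> outcome
# reports, with all artifacts written to an output directory.

#' Pipeline run configuration
#'
#' @param phantom a `phantom_spec`, or a path to a phantom-spec YAML, or a
#'   path to a NIfTI labelmap (then `orbit_region` must be supplied by the
#'   caller of [run_pipeline()]).
#' @param plans list of plan specifications (see [write_plan_spec()]) or
#'   paths to plan YAML files.
#' @param materials a `material_params`.
#' @param target_edge mesh cell edge, mm.
#' @param n_steps incremental load steps.
#' @param pitch outcome rasterisation pitch, mm.
#' @param output_dir directory for artifacts.
#' @param seed integer seed recorded and applied at the start of the run.
#' @param formats artifact formats to write (subset of `"vtu"`, `"csv"`,
#'   `"json"`, `"nifti"`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), plans = default_plan_specs(),
                       materials = material_params(), target_edge = 2,
                       n_steps = 10L, pitch = 0.5,
                       output_dir = tempfile("orbdecomp_run_"),
                       seed = 1L, formats = c("vtu", "csv", "json")) {
  structure(list(phantom = phantom, plans = plans, materials = materials,
                 target_edge = target_edge, n_steps = as.integer(n_steps),
                 pitch = pitch, output_dir = output_dir,
                 seed = as.integer(seed), formats = formats),
            class = "run_config")
}

#' Default scenario pair: lateral valgization vs two-wall resection
#'
#' The valgization scenario shifts the lateral wall fragment 2.5 mm and
#' rotates it 30 degrees about its anterior hinge; the resection scenario
#' opens the lateral and floor walls under the same intraorbital pressure.
#'
#' @param pressure_kPa intraorbital pressure shared by both scenarios.
#' @return List of two plan specifications.
#' @export
default_plan_specs <- function(pressure_kPa = 1.2) {
  list(
    list(id = "lava", scenario = "VALGIZATION",
         fragments = list(list(wall_tag = "LATERAL_WALL")),
         shift_mm = 2.5, angle_deg = 30, pressure_kPa = pressure_kPa),
    list(id = "twowall", scenario = "RESECTION",
         fragments = list(list(wall_tag = "LATERAL_WALL"),
                          list(wall_tag = "FLOOR_WALL")),
         pressure_kPa = pressure_kPa))
}

#' Run the full simulation pipeline
#'
#' Generates (or loads) the orbital model, builds the tetrahedral mesh,
#' realises and simulates every plan, computes outcome reports and the
#' scenario comparison, and writes all artifacts (labelmap, meshes,
#' displacement fields, CSV/JSON reports, run log) under
#' `config$output_dir`.  Deterministic for a fixed config and seed.
#'
#' @param config a `run_config`.
#' @param orbit_region optional cavity signed-distance override (required
#'   when `config$phantom` is a labelmap path).
#' @return Object of class `pipeline_result`: reports, comparison, mesh,
#'   fields, paths of written artifacts.
#' @export
run_pipeline <- function(config, orbit_region = NULL) {
  set.seed(config$seed)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run_log.txt")
  logcon <- file(logf, "w")
  log <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logcon)
    invisible(msg)
  }
  on.exit(close(logcon))
  log("orbdecomp pipeline run")
  log("R version: %s; orbdecomp %s", R.version.string,
      tryCatch(as.character(utils::packageVersion("orbdecomp")),
               error = function(e) "(source)"))
  log("seed: %d", config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- phantom / labelmap
  ph <- NULL
  volume <- NULL
  phantom <- config$phantom
  if (is.character(phantom)) {
    if (grepl("\\.ya?ml$", phantom)) phantom <- read_phantom_spec(phantom)
    else {
      volume <- stage("phantom", load_labelmap(phantom))
      log("loaded labelmap %s", config$phantom)
    }
  }
  if (inherits(phantom, "phantom_spec")) {
    ph <- stage("phantom", generate_phantom(phantom))
    volume <- ph$volume
    if (is.null(orbit_region)) orbit_region <- ph$ground_truth$orbit_region
    log("phantom generated: %s voxels at %.3g mm",
        paste(dim(volume$labels), collapse = "x"), volume$voxel_size)
  }
  if (is.null(orbit_region))
    stopf("pipeline stage 'phantom' failed: no orbital cavity descriptor available")
  if ("nifti" %in% config$formats)
    stage("phantom", save_labelmap(volume, file.path(out, "labelmap.nii.gz")))

  # --- mesh
  mesh <- stage("mesh", build_tet_mesh(volume, target_edge = config$target_edge))
  q <- mesh_quality(mesh)
  log("mesh: %d nodes, %d tets; min dihedral %.2f deg, max aspect %.1f, %d inverted",
      nrow(mesh$nodes), nrow(mesh$tets), q$min_dihedral_deg, q$max_aspect,
      q$n_inverted)
  if (q$n_inverted > 0)
    stopf("pipeline stage 'mesh' failed: %d inverted tets", q$n_inverted)
  if ("vtu" %in% config$formats)
    write_vtu(mesh, file.path(out, "mesh.vtu"))

  # --- plans + simulation + outcome
  reports <- list()
  fields <- list()
  for (pspec in config$plans) {
    if (is.character(pspec)) pspec <- read_plan_spec(pspec)
    plan <- stage(paste0("plan:", pspec$id %||% pspec$scenario),
                  realize_plan(pspec, mesh))
    log("plan '%s' (%s): area %.2f cm^2, pressure %.3g kPa", plan$id,
        plan$scenario, sum(vapply(plan$fragments, `[[`, 0, "area_cm2")),
        plan$pressure_kPa)
    fld <- stage(paste0("simulate:", plan$id),
                 simulate_scenario(mesh, plan, config$materials,
                                   n_steps = config$n_steps))
    rep <- stage(paste0("outcome:", plan$id),
                 outcome_report(plan$id, mesh, fld, orbit_region,
                                pitch = config$pitch))
    log("outcome '%s': released %.3f cm^3 over %.2f cm^2 (ratio %.3f), proptosis %+0.2f mm",
        plan$id, rep$released_cm3, rep$area_cm2, rep$volume_per_area,
        rep$proptosis_mm)
    reports[[plan$id]] <- rep
    fields[[plan$id]] <- fld
    if ("vtu" %in% config$formats)
      write_vtu(mesh, file.path(out, sprintf("field_%s.vtu", plan$id)),
                nodes = mesh$nodes + fld$u,
                point_data = list(displacement = fld$u,
                                  outside_cavity =
                                    as.numeric(orbit_region(mesh$nodes + fld$u) > 0)))
  }

  comparison <- NULL
  if (length(reports) >= 2L) {
    comparison <- stage("compare", compare_scenarios(reports))
    if ("csv" %in% config$formats)
      write_comparison(comparison, csv = file.path(out, "comparison.csv"))
    if ("json" %in% config$formats)
      write_comparison(comparison, json = file.path(out, "comparison.json"))
  }

  # config echo for reproducibility
  cfgecho <- config
  cfgecho$materials <- list(E = as.list(config$materials$E),
                            nu = as.list(config$materials$nu))
  if (inherits(cfgecho$phantom, "phantom_spec")) {
    pe <- unclass(cfgecho$phantom)
    pe$wall_region_angles <- as.list(pe$wall_region_angles)
    cfgecho$phantom <- pe
  }
  yaml::write_yaml(unclass(cfgecho), file.path(out, "config_echo.yaml"))
  log("defaults applied: target_edge %.3g mm, n_steps %d, pitch %.3g mm",
      config$target_edge, config$n_steps, config$pitch)

  structure(list(reports = reports, comparison = comparison, mesh = mesh,
                 fields = fields, output_dir = out,
                 volume = volume, orbit_region = orbit_region),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d scenario(s), artifacts in %s\n",
              length(x$reports), x$output_dir))
  if (!is.null(x$comparison)) print(x$comparison)
  else for (r in x$reports) print(r)
  invisible(x)
}
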