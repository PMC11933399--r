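#' Derive a stage sub-seed
#'
#' Every stochastic stage of [run_pipeline()] consumes a sub-seed derived
#' deterministically from the master seed as
#' `(seed + 99991 * stage_index) mod (2^31 - 1)`, so one seed reproduces
#' the whole run while stages stay decoupled.
#'
#' @param seed Master integer seed.
#' @param stage Stage index (integer).
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) + 99991 * stage) %% 2147483647)
}

#' Assemble a pipeline configuration
#'
#' @param seed Master seed.
#' @param standards_source `"WHO_EPA"` or `"SriLanka"`.
#' @param n_districts,n_wells,total_population Synthetic-world sizes.
#' @param grid_cell_km Interpolation/truth raster resolution (km).
#' @param correlation_length,cv,cluster_cor True-field settings
#'   (see [generate_true_fields()]).
#' @param noise_cv Well measurement noise.
#' @param variogram_model Variogram family for ordinary kriging.
#' @param idw_power,idw_neighbors IDW settings (nitrate routing).
#' @param log_transform Krige concentrations in log space.
#' @param n_trees,max_iter Random-forest imputation settings.
#' @param exposure_threshold Hazard-index cutoff defining an exposed
#'   district.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A `"run_config"` list.
#' @export
run_config <- function(seed = 1, standards_source = "WHO_EPA",
                       n_districts = 25, n_wells = 688,
                       total_population = 22e6, grid_cell_km = 2,
                       correlation_length = 40, cv = 0.8, cluster_cor = 0.8,
                       noise_cv = 0.05,
                       variogram_model = "spherical",
                       idw_power = 2, idw_neighbors = 12,
                       log_transform = TRUE,
                       n_trees = 100, max_iter = 10,
                       exposure_threshold = 0.2,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error,
#' absent keys take the defaults.
#'
#' @param path YAML file.
#' @param overrides Named list applied on top of the file (e.g. CLI
#'   flags).
#' @return A `"run_config"`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Interpolate all index parameters
#'
#' Routes each parameter to its interpolator — inverse distance weighting
#' for Nitrate (to preserve local variation), ordinary kriging with a
#' fitted variogram for everything else — using observed (non-imputed)
#' values only, and collects leave-one-out standardized-RMSE diagnostics
#' for the kriged parameters.
#'
#' @param wells A `"well_table"` (may contain missing values).
#' @param spec A `"grid_spec"`.
#' @param parameters Parameters to interpolate.
#' @param idw_parameters Parameters routed to IDW (default `"Nitrate"`).
#' @param variogram_model Variogram family.
#' @param idw_power,idw_neighbors IDW settings.
#' @param log_transform Krige in log space (variograms are then fitted to
#'   log values).
#' @param loo Compute leave-one-out diagnostics (default `TRUE`).
#' @return List: `grids` (named list of `"parameter_grid"`),
#'   `diagnostics` (data.frame: parameter, method, n_points, nugget, sill,
#'   range, loo_srmse).
#' @export
interpolate_parameters <- function(wells, spec,
                                   parameters = intersect(index_parameters(), names(wells)),
                                   idw_parameters = "Nitrate",
                                   variogram_model = "spherical",
                                   idw_power = 2, idw_neighbors = 12,
                                   log_transform = TRUE, loo = TRUE) {
  grids <- list()
  diag_rows <- list()
  for (p in parameters) {
    if (p %in% idw_parameters) {
      grids[[p]] <- idw(wells, p, power = idw_power, spec = spec,
                        max_neighbors = idw_neighbors)
      diag_rows[[p]] <- data.frame(parameter = p, method = "idw",
                                   n_points = grids[[p]]$n_points,
                                   nugget = NA, sill = NA, range = NA,
                                   loo_srmse = NA)
    } else {
      w <- wells
      if (log_transform) w[[p]] <- log(w[[p]])
      vm <- fit_variogram(w, p, model = variogram_model)
      grids[[p]] <- krige(wells, p, vm, spec, log_transform = log_transform)
      srmse <- if (loo && !isTRUE(attr(vm, "degenerate")))
        as.numeric(loo_standardized_rmse(wells, p, vm,
                                         log_transform = log_transform))
      else NA_real_
      diag_rows[[p]] <- data.frame(parameter = p, method = "ordinary_kriging",
                                   n_points = grids[[p]]$n_points,
                                   nugget = vm$nugget, sill = vm$sill,
                                   range = vm$range, loo_srmse = srmse)
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  list(grids = grids, diagnostics = diagnostics)
}

#' Run the full analysis pipeline
#'
#' Simulate -> impute -> interpolate -> WQI -> hazard (both methods) ->
#' exposure, writing every product plus a manifest and a summary JSON to
#' `config$out_dir`. Re-running with the same configuration reproduces
#' identical outputs.
#'
#' @param config A `"run_config"`.
#' @return Invisibly, a list with all in-memory products (`districts`,
#'   `fields`, `wells_complete`, `wells`, `imputation`, `interpolation`,
#'   `truth`, `wqi`, `hazard_interpolated`, `hazard_imputed`,
#'   `exposure_interpolated`, `exposure_imputed`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  standards <- load_standards(config$standards_source)
  districts <- generate_districts(config$n_districts, derive_seed(config$seed, 1),
                                  total_population = config$total_population)
  fields <- generate_true_fields(districts,
                                 correlation_length = config$correlation_length,
                                 cv = config$cv, cluster_cor = config$cluster_cor,
                                 seed = derive_seed(config$seed, 2),
                                 cell_size = config$grid_cell_km)
  wells_complete <- sample_wells(fields, districts, config$n_wells,
                                 seed = derive_seed(config$seed, 3),
                                 noise_cv = config$noise_cv)
  wells <- apply_missingness(wells_complete, seed = derive_seed(config$seed, 4))
  truth <- true_district_exceedance(fields, districts, standards)

  imp <- rf_impute(wells, n_trees = config$n_trees, max_iter = config$max_iter,
                   seed = derive_seed(config$seed, 5))
  mask <- missing_mask(wells)
  imp_nrmse <- as.numeric(nrmse(wells_complete, imp$completed, mask))

  spec <- grid_spec_for(districts, config$grid_cell_km)
  interp <- interpolate_parameters(
    wells, spec, variogram_model = config$variogram_model,
    idw_power = config$idw_power, idw_neighbors = config$idw_neighbors,
    log_transform = config$log_transform)

  wqi_tab <- district_wqi(imp$completed, districts, standards)
  hz_interp <- hazard_by_interpolation(interp$grids, districts, standards)
  hz_imp <- hazard_by_imputation(imp, districts, standards)
  hz_interp$hazard_class <- as.character(classify_hazard(hz_interp$index))
  hz_imp$hazard_class <- as.character(classify_hazard(hz_imp$index))
  exp_interp <- population_exposure(hz_interp, districts,
                                    config$exposure_threshold)
  exp_imp <- population_exposure(hz_imp, districts, config$exposure_threshold)

  summary <- list(
    seed = config$seed,
    n_wells = config$n_wells,
    n_districts = config$n_districts,
    standards_source = config$standards_source,
    imputation = list(overall_nrmse = imp_nrmse,
                      overall_oob_nrmse = imp$overall_oob_nrmse,
                      n_iterations = imp$n_iterations,
                      converged = imp$converged),
    mean_loo_srmse = mean(interp$diagnostics$loo_srmse, na.rm = TRUE),
    hazard = list(
      interpolated = list(min = min(hz_interp$index), max = max(hz_interp$index)),
      imputed = list(min = min(hz_imp$index), max = max(hz_imp$index))
    ),
    exposure = list(
      threshold = config$exposure_threshold,
      interpolated = list(exposed = attr(exp_interp, "national_exposed"),
                          percent = attr(exp_interp, "national_percent")),
      imputed = list(exposed = attr(exp_imp, "national_exposed"),
                     percent = attr(exp_imp, "national_percent")),
      national_total = attr(exp_interp, "national_total")
    )
  )

  if (!is.null(out_dir)) {
    write_wells(wells_complete, file.path(out_dir, "wells_complete.csv"))
    write_wells(wells, file.path(out_dir, "wells.csv"))
    write_wells(imp$completed, file.path(out_dir, "imputed.csv"))
    write_districts(districts, file.path(out_dir, "districts.geojson"))
    utils::write.csv(truth, file.path(out_dir, "truth_exceedance.csv"),
                     row.names = FALSE)
    gdir <- file.path(out_dir, "grids")
    dir.create(gdir, showWarnings = FALSE)
    for (p in names(interp$grids))
      write_grid_ascii(interp$grids[[p]], file.path(gdir, paste0(p, ".asc")))
    utils::write.csv(interp$diagnostics,
                     file.path(out_dir, "interpolation_diagnostics.csv"),
                     row.names = FALSE)
    utils::write.csv(wqi_tab, file.path(out_dir, "wqi.csv"), row.names = FALSE)
    utils::write.csv(rbind(hz_interp, hz_imp), file.path(out_dir, "hazard.csv"),
                     row.names = FALSE)
    exp_out <- rbind(
      cbind(method = "interpolated", as.data.frame(exp_interp)),
      cbind(method = "imputed", as.data.frame(exp_imp)))
    utils::write.csv(exp_out, file.path(out_dir, "exposure.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_plain <- unclass(config); cfg_plain$out_dir <- NULL
    files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("aquahazard")),
      config = cfg_plain,
      checksums = as.list(tools::md5sum(files))
    )
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(districts = districts, fields = fields,
                 wells_complete = wells_complete, wells = wells,
                 imputation = imp, interpolation = interp, truth = truth,
                 wqi = wqi_tab, hazard_interpolated = hz_interp,
                 hazard_imputed = hz_imp, exposure_interpolated = exp_interp,
                 exposure_imputed = exp_imp, summary = summary))
}
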