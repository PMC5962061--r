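# Pipeline driver: declarative configuration, the end-to-end run, and the
# seeded demo fixture.

#' Pipeline configuration
#'
#' Collects every analysis constant in one validated object: strip
#' bandwidth (1400 m), terminal-remainder rule, forest-exclusion threshold
#' (0.95), collinearity threshold (0.4), basis-dimension range (4-20),
#' Tweedie power policy, autocorrelation trigger (0.15), prediction cell
#' area (1.96 km^2), candidate model list and the root seed. The
#' configuration round-trips losslessly through YAML.
#'
#' @param bandwidth Strip width, m.
#' @param min_fraction Minimum kept fraction of a terminal remainder.
#' @param forest_threshold Exclusion threshold on forest fraction.
#' @param collinearity_threshold |r| above which covariates go in separate
#'   models.
#' @param k_min,k_max Basis-dimension range.
#' @param p Tweedie power (or `"profile"` to profile over 1.1-1.9).
#' @param acf_threshold Residual-correlation trigger for AR(1) correction.
#' @param cell_area Prediction-grid cell area, km^2.
#' @param candidates Candidate model labels.
#' @param select_k Search basis dimensions by REML during candidate fits.
#' @param seed Root seed; sub-generators derive their streams from it.
#' @return A validated `dsm_config` list.
#' @export
pipeline_config <- function(bandwidth = 1400, min_fraction = 0.5,
                            forest_threshold = 0.95,
                            collinearity_threshold = 0.4,
                            k_min = 4, k_max = 20, p = 1.5,
                            acf_threshold = 0.15, cell_area = 1.96,
                            candidates = c("AA+GL", "DC+GL", "GL",
                                           "AA:GL", "DC:GL", "AA", "DC"),
                            select_k = FALSE, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "dsm_config")
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config A `dsm_config`.
#' @export
validate_config <- function(config) {
  with(config, {
    if (bandwidth <= 0) abort("bandwidth must be > 0", class = "invalid_config")
    if (min_fraction < 0 || min_fraction > 1) abort("min_fraction must be in [0, 1]", class = "invalid_config")
    if (forest_threshold <= 0 || forest_threshold > 1) abort("forest_threshold must be in (0, 1]", class = "invalid_config")
    if (collinearity_threshold < 0 || collinearity_threshold > 1) abort("collinearity_threshold must be in [0, 1]", class = "invalid_config")
    if (k_min < 4 || k_max > 20 || k_min > k_max) abort("k range must lie within [4, 20]", class = "invalid_config")
    if (is.numeric(p) && (p < 1 || p > 2)) abort("p must lie in [1, 2]", class = "invalid_config")
    if (acf_threshold <= 0 || acf_threshold >= 1) abort("acf_threshold must be in (0, 1)", class = "invalid_config")
    if (cell_area <= 0) abort("cell_area must be > 0", class = "invalid_config")
  })
  invisible(config)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full density-surface pipeline on one season of survey data
#'
#' Segmentation, covariate summary, collinearity screening, candidate
#' fitting and REML selection, residual-autocorrelation diagnosis with
#' AR(1) correction and term pruning when triggered, grid prediction and
#' uncertainty. Inputs are in-memory objects; when `out_dir` is given,
#' every stage's table is also written (segments, candidate table, ACF
#' report, model file, surface, JSON summary) and inputs are never
#' modified.
#'
#' @param config A [pipeline_config()].
#' @param landscape A `dsm_landscape`.
#' @param flight_paths Path-vertex tibble.
#' @param records Sighting records tibble.
#' @param season Season label.
#' @param out_dir Optional output directory.
#' @return A `dsm_run` list: `segments`, `screen`, `candidates`,
#'   `acf`, `fit` (final), `fit_gam` (pre-correction best), `surface`,
#'   `uncertainty`, `summary`.
#' @export
run_pipeline <- function(config, landscape, flight_paths, records,
                         season = "season", out_dir = NULL) {
  validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "pipeline_error", parent = e)
    })
  }
  segments <- stage("segmentation", {
    seg <- segmentize_transects(flight_paths, bandwidth = config$bandwidth,
                                min_fraction = config$min_fraction, season = season)
    seg <- assign_records(seg, records, bandwidth = config$bandwidth)
    summarize_covariates(seg, landscape, forest_threshold = config$forest_threshold)
  })
  screen <- stage("screening",
    collinearity_screen(segments[!segments$excluded, ],
                        .data$mean_elevation, .data$distance_to_coast,
                        threshold = config$collinearity_threshold))
  candidates <- config$candidates
  cand_tbl <- stage("candidates",
    run_candidates(segments, candidates = candidates,
                   p = if (identical(config$p, "profile")) 1.5 else config$p,
                   select_k = config$select_k,
                   k_grid = unique(pmin(config$k_max, pmax(config$k_min, c(4, 8, 12, 16, 20))))))
  fit_gam <- best_fit(cand_tbl)
  acf_rep <- stage("autocorrelation", residual_acf(fit_gam))
  fit_final <- fit_gam
  comparison <- NULL
  if (any(!is.na(acf_rep$correlation) & acf_rep$correlation > config$acf_threshold)) {
    fit_final <- stage("ar1-correction", {
      f <- fit_ar1(segments, model = fit_gam$label, rho = "estimate",
                   p = fit_gam$p)
      prune_terms(f, segments, alpha = 0.05, rho = f$rho)
    })
  }
  grid <- stage("grid", build_grid(landscape, cell_area = config$cell_area,
                                   forest_threshold = config$forest_threshold))
  surface <- stage("prediction", predict_cells(fit_final, grid))
  unc <- stage("uncertainty", dsm_uncertainty(fit_final, grid))
  if (!identical(fit_final, fit_gam)) {
    comparison <- compare_gam_gamm(fit_gam, fit_final, grid)
  }
  tot <- total_abundance(surface)
  summary <- list(
    season = season, model = fit_final$label, rho = fit_final$rho,
    pearson_r = screen$r, separate_models = screen$separate_models,
    n_segments = nrow(segments), n_excluded_segments = sum(segments$excluded),
    total_count = sum(segments$count),
    unassigned_individuals = sum(unassigned_records(segments)$group_size),
    grid_cells = unname(attr(grid, "counts")["total"]),
    grid_excluded = unname(attr(grid, "counts")["excluded"]),
    grid_retained = unname(attr(grid, "counts")["retained"]),
    abundance = tot$abundance, density = tot$density,
    cv = unc$total$cv,
    deviance_explained = fit_final$deviance_explained,
    acf = stats::setNames(acf_rep$correlation, paste0("lag", acf_rep$lag)),
    acf_triggered = acf_triggered(acf_rep),
    reml = fit_final$reml,
    config = unclass(config))
  run <- structure(
    list(segments = segments, screen = screen, candidates = cand_tbl,
         acf = acf_rep, fit = fit_final, fit_gam = fit_gam,
         comparison = comparison, grid = grid, surface = surface,
         uncertainty = unc, summary = summary),
    class = "dsm_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_segments_csv(segments, file.path(out_dir, paste0("segments_", season, ".csv")))
    readr::write_csv(dplyr::select(cand_tbl, -"k"), file.path(out_dir, paste0("candidates_", season, ".csv")))
    readr::write_csv(acf_rep, file.path(out_dir, paste0("acf_", season, ".csv")))
    write_dsm_model(fit_final, file.path(out_dir, paste0("model_", season, ".json")))
    readr::write_csv(surface, file.path(out_dir, paste0("surface_", season, ".csv")))
    jsonlite::write_json(summary, file.path(out_dir, paste0("summary_", season, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  run
}

#' @export
print.dsm_run <- function(x, ...) {
  s <- x$summary
  cat("<dsm_run> ", s$season, ": model ", s$model,
      if (s$rho != 0) paste0(" (AR1 rho = ", round(s$rho, 2), ")") else "",
      "\n  abundance ", round(s$abundance), " (CV ", round(100 * s$cv, 1),
      "%), density ", round(s$density, 2), " ind/km^2\n", sep = "")
  invisible(x)
}

#' Write a seeded demo dataset with known truth
#'
#' Generates a small landscape, two seasons of systematic flight paths and
#' survey records (on the order of 30 segments per season), writes them in
#' the package's exchange formats (ASCII grid, GeoJSON, CSV) together with
#' a `truth.json` holding the simulated total abundance and generator
#' settings, for use in recovery tests and examples.
#'
#' @param dir Output directory (created if needed).
#' @param seed Root seed.
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
make_fixture <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ls <- simulate_landscape(extent_km = c(21, 15.4), cell_size = 700,
                           elevation_params = list(mean = 400, sd = 200, range_km = 5),
                           forest_params = list(mean = 0.2, range_km = 3, steep = 3),
                           seed = seed)
  paths <- make_flight_paths(ls, n_transects = 3)
  models <- list(
    `non-breeding` = intensity_model(
      intercept = log(1.2), season = "non-breeding",
      elevation = function(e) -0.0012 * (e - 400),
      group_size = list(dist = "ztnb", mean = 3, size = 1.5)),
    breeding = intensity_model(
      intercept = log(1.2), season = "breeding",
      coast = function(d) 4e-5 * (d - 10000),
      group_size = list(dist = "ztnb", mean = 3, size = 1.5)))
  out <- list(landscape = ls, flight_paths = paths, records = list(), truth = list())
  write_ascii_grid(ls$elevation, file.path(dir, "elevation.asc"),
                   origin = ls$origin, cell_size = ls$cell_size)
  write_ascii_grid(ls$forest_fraction, file.path(dir, "forest.asc"),
                   origin = ls$origin, cell_size = ls$cell_size)
  write_paths_geojson(paths, file.path(dir, "flight_paths.geojson"))
  write_paths_geojson(tibble::tibble(transect_id = "coast",
                                     x = ls$coastline[, 1], y = ls$coastline[, 2]),
                      file.path(dir, "coastline.geojson"))
  truth <- list(seed = seed, seasons = list())
  for (season in names(models)) {
    sseed <- seed + match(season, names(models))
    pop <- simulate_population(ls, models[[season]], seed = sseed)
    surv <- simulate_survey(pop, paths, bandwidth = 1400, seed = sseed)
    write_records_csv(surv$records, file.path(dir, paste0("records_", season, ".csv")))
    out$records[[season]] <- surv$records
    truth$seasons[[season]] <- list(
      total_abundance = sum(pop$group_size),
      n_groups = nrow(pop),
      detected_individuals = sum(surv$records$group_size),
      intercept = models[[season]]$intercept,
      mean_group_size = mean(pop$group_size))
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  out$truth <- truth
  invisible(out)
}
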