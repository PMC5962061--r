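# Shared desk-scale fixtures, built once per test run.

# Small landscape + systematic survey with a known elevation effect on
# log density; used by fitting, selection and prediction tests.
demo_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ls1 <- simulate_landscape(extent_km = c(28, 21), cell_size = 700,
                              elevation_params = list(mean = 450, sd = 220, range_km = 5),
                              forest_params = list(mean = 0.2, range_km = 3, steep = 3),
                              seed = 101)
    paths <- make_flight_paths(ls1, n_transects = 5)
    truth_fun <- function(e) -0.0015 * (e - 450)
    im <- intensity_model(intercept = log(1.6), elevation = truth_fun,
                          group_size = list(dist = "ztnb", mean = 3, size = 1.5))
    pop <- simulate_population(ls1, im, seed = 102)
    surv <- simulate_survey(pop, paths, bandwidth = 1400, seed = 103)
    seg <- segmentize_transects(paths, bandwidth = 1400, min_fraction = 0.5,
                                season = "demo")
    seg <- assign_records(seg, surv$records)
    seg <- summarize_covariates(seg, ls1)
    cache <<- list(landscape = ls1, paths = paths, model = im,
                   truth_fun = truth_fun, population = pop, survey = surv,
                   segments = seg)
    cache
  }
})

# One survey replicate at the full design scale (~600 segments), with an
# elevation-driven population; returns segments plus the truth needed for
# recovery checks.
simulate_design_survey <- function(rep_seed,
                                   effect = function(e) -0.0015 * (e - 500),
                                   intercept = log(1.1)) {
  ls1 <- simulate_landscape(seed = rep_seed)
  paths <- make_flight_paths(ls1, n_transects = 12)
  im <- intensity_model(intercept = intercept, elevation = effect,
                        group_size = list(dist = "ztnb", mean = 3, size = 1.5))
  pop <- simulate_population(ls1, im, seed = rep_seed + 1000)
  surv <- simulate_survey(pop, paths, bandwidth = 1400, seed = rep_seed)
  seg <- segmentize_transects(paths, bandwidth = 1400, min_fraction = 0.5)
  seg <- assign_records(seg, surv$records)
  seg <- summarize_covariates(seg, ls1)
  list(landscape = ls1, population = pop, survey = surv, segments = seg,
       effect = effect)
}

# Segment table with iid counts and no spatial structure, for pure fitting
# machinery tests.
toy_segments <- function(n = 40, seed = 1, mu = 5, n_transects = 2) {
  withr::with_seed(seed, tibble::tibble(
    count = rpois(n, mu),
    area_km2 = 1,
    mean_elevation = runif(n, 0, 1000),
    distance_to_coast = runif(n, 0, 40000),
    x = runif(n, 0, 50000), y = runif(n, 0, 50000),
    transect_id = rep(sprintf("T%d", seq_len(n_transects)), length.out = n),
    seg_idx = as.integer(stats::ave(seq_len(n),
      rep(sprintf("T%d", seq_len(n_transects)), length.out = n),
      FUN = seq_along))))
}
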