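#' Define a seasonal intensity model for the simulated population
#'
#' The log expected density of groups per km^2 at a location is
#' `intercept + f_elev(elevation) + f_coast(dist_to_coast) + f_xy(x, y)`,
#' mirroring the smooth structure the abundance model fits. Group sizes are
#' drawn from a zero-truncated negative binomial (configurable to a point
#' mass at 1), since observed group counts in aerial surveys of social
#' ungulates are overdispersed.
#'
#' @param intercept Log density of groups per km^2 at covariate effect 0.
#' @param elevation,coast,location Optional effect functions on the log
#'   scale: `elevation(elev_m)`, `coast(dist_m)`, `location(x, y)`.
#' @param p Tweedie power in (1, 2) describing the intended response family.
#' @param phi Tweedie dispersion (> 0), metadata for the intended family.
#' @param season Season label carried through the pipeline.
#' @param group_size List: `dist` one of `"ztnb"` (zero-truncated negative
#'   binomial; `mean` and `size` parameterize the untruncated NB) or
#'   `"constant"` (`value` individuals per group).
#' @return An `intensity_model` object.
#' @export
intensity_model <- function(intercept = log(1),
                            elevation = NULL, coast = NULL, location = NULL,
                            p = 1.5, phi = 2, season = "non-breeding",
                            group_size = list(dist = "ztnb", mean = 3, size = 1.5)) {
  if (!(is.numeric(p) && p > 1 && p < 2)) {
    abort("Tweedie power `p` must lie strictly in (1, 2).", class = "invalid_argument")
  }
  if (phi <= 0) abort("`phi` must be > 0.", class = "invalid_argument")
  gs <- utils::modifyList(list(dist = "ztnb", mean = 3, size = 1.5), group_size)
  structure(
    list(intercept = intercept, elevation = elevation, coast = coast,
         location = location, p = p, phi = phi, season = season,
         group_size = gs),
    class = "intensity_model")
}

# Expected group density (groups per km^2) at points of a landscape.
intensity_at <- function(model, landscape, x, y) {
  eta <- rep(model$intercept, length(x))
  if (!is.null(model$elevation)) {
    eta <- eta + model$elevation(raster_lookup(landscape, x, y, "elevation"))
  }
  if (!is.null(model$coast)) {
    eta <- eta + model$coast(coast_distance(landscape, x, y))
  }
  if (!is.null(model$location)) {
    eta <- eta + model$location(x, y)
  }
  exp(eta)
}

#' Simulate a population of groups over a landscape
#'
#' Places groups by an inhomogeneous Poisson point process: the expected
#' number of groups in a raster cell is the intensity at the cell center
#' times the cell area (km^2); group positions are uniform within their
#' cell and group sizes are drawn from the model's group-size distribution.
#'
#' @param landscape A `dsm_landscape`.
#' @param model An [intensity_model()].
#' @param seed Integer seed; the population is deterministic given the seed.
#' @return A tibble of groups: `x`, `y` (m) and `group_size` (>= 1).
#' @export
simulate_population <- function(landscape, model, seed = 1L) {
  cells <- as_tibble.dsm_landscape(landscape)
  lambda <- intensity_at(model, landscape, cells$x, cells$y)
  if (any(is.nan(lambda)) || any(is.na(lambda)) || any(is.infinite(lambda))) {
    abort("Intensity is not finite everywhere on the landscape.", class = "invalid_model")
  }
  area_km2 <- (landscape$cell_size / 1000)^2
  withr::with_seed(seed, {
    n_groups <- rpois(nrow(cells), lambda * area_km2)
    idx <- rep.int(seq_len(nrow(cells)), n_groups)
    n <- length(idx)
    if (n == 0) {
      return(tibble::tibble(x = numeric(), y = numeric(), group_size = integer()))
    }
    half <- landscape$cell_size / 2
    tibble::tibble(
      x = cells$x[idx] + runif(n, -half, half),
      y = cells$y[idx] + runif(n, -half, half),
      group_size = draw_group_sizes(n, model$group_size))
  })
}

draw_group_sizes <- function(n, gs) {
  if (identical(gs$dist, "constant")) {
    return(rep(as.integer(gs$value %||% 1L), n))
  }
  # zero-truncated NB by inversion: sample the cdf above P(X = 0)
  p0 <- pnbinom(0, mu = gs$mean, size = gs$size)
  u <- runif(n, p0, 1)
  as.integer(qnbinom(u, mu = gs$mean, size = gs$size))
}

#' Simulate a strip-transect survey over a population
#'
#' Implements the strip-transect observation model: every group whose
#' perpendicular distance to a flight path is at most `bandwidth / 2` is
#' detected with certainty; groups outside every strip are never detected
#' (detection probability 1 inside the strip, 0 outside). Strips have flat
#' caps: a group beyond the end of a transect is not detected even if it is
#' close to the terminal vertex. Timestamps are synthesized monotonically
#' along each path in survey order.
#'
#' @param population Tibble of groups from [simulate_population()].
#' @param flight_paths Tibble of path vertices (`transect_id`, `x`, `y`).
#' @param bandwidth Strip width in meters (default 1400, i.e. 700 m each side).
#' @param seed Integer recorded in the realization (the observation model
#'   itself is deterministic).
#' @return A `dsm_survey` object: `individuals` (the simulated population),
#'   `flight_paths`, `records` (detected groups with `x`, `y`, `group_size`,
#'   `t` seconds from survey start), `bandwidth`, `seed`.
#' @export
simulate_survey <- function(population, flight_paths, bandwidth = 1400, seed = 1L) {
  if (bandwidth <= 0) abort("`bandwidth` must be > 0.", class = "invalid_argument")
  if (is.null(flight_paths) || nrow(flight_paths) == 0) {
    abort("`flight_paths` is empty.", class = "invalid_argument")
  }
  paths <- split(flight_paths[c("x", "y")], flight_paths$transect_id)
  pts <- cbind(population$x, population$y)
  n <- nrow(population)
  best_d <- rep(Inf, n); best_path <- rep(NA_character_, n); best_along <- rep(NA_real_, n)
  offset_along <- 0
  for (id in names(paths)) {
    pm <- as.matrix(paths[[id]])
    if (n > 0) {
      pr <- project_on_polyline(pts, pm)
      upd <- pr$dist < best_d
      best_d[upd] <- pr$dist[upd]
      best_path[upd] <- id
      best_along[upd] <- pr$along[upd] + offset_along
    }
    offset_along <- offset_along + polyline_length(pm)
  }
  det <- which(best_d <= bandwidth / 2)
  ord <- det[order(best_along[det])]
  records <- tibble::tibble(
    x = population$x[ord], y = population$y[ord],
    group_size = population$group_size[ord],
    t = if (length(ord)) 10 * seq_along(ord) else numeric())
  structure(
    list(individuals = population, flight_paths = flight_paths,
         records = records, bandwidth = bandwidth, seed = seed),
    class = "dsm_survey")
}

#' @export
print.dsm_survey <- function(x, ...) {
  cat("<dsm_survey> ", nrow(x$records), " of ", nrow(x$individuals),
      " groups detected in a ", x$bandwidth, " m strip (",
      sum(x$records$group_size), " individuals)\n", sep = "")
  invisible(x)
}
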