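#' Simulate a study landscape
#'
#' Generates a rectangular raster landscape on a projected plane (meters):
#' a smooth random elevation field whose correlation with distance to the
#' coast is tunable, a patchy forest-fraction field in \[0, 1\], and a
#' coastline polyline. By default the coastline is the western edge of the
#' rectangle, which makes distance to coast analytic (x minus the western
#' origin) and easy to test against.
#'
#' The elevation surface is built as a convex combination of the (scaled)
#' distance-to-coast trend and a Gaussian random field obtained by separable
#' kernel smoothing of white noise, so that the sample Pearson correlation
#' between per-cell elevation and distance to coast is approximately
#' `elevation_params$coast_cor`. Elevation is truncated below at sea level.
#'
#' @param extent_km Numeric of length 1 (square) or 2 (width, height) in km.
#' @param cell_size Raster resolution in meters.
#' @param elevation_params List: `mean` and `sd` in meters, `range_km`
#'   (smoothing length of the random field), `coast_cor` (target Pearson
#'   correlation between elevation and distance to coast).
#' @param forest_params List: `mean` (target mean forest fraction),
#'   `range_km` (patch scale), `steep` (logit-scale spread; larger values
#'   produce more cells near 0 and 1).
#' @param seed Integer seed; the landscape is deterministic given the seed.
#' @return A `dsm_landscape` object: origin, cell size, elevation and
#'   forest-fraction matrices (rows run south to north), and the coastline.
#' @examples
#' ls <- simulate_landscape(extent_km = c(20, 15), cell_size = 700, seed = 1)
#' dplyr::glimpse(tibble::as_tibble(ls))
#' @export
simulate_landscape <- function(extent_km = c(68.6, 103.6),
                               cell_size = 1400,
                               elevation_params = list(),
                               forest_params = list(),
                               seed = 1L) {
  if (any(extent_km <= 0) || cell_size <= 0) {
    abort("`extent_km` and `cell_size` must be positive.", class = "invalid_argument")
  }
  if (length(extent_km) == 1) extent_km <- c(extent_km, extent_km)
  ep <- utils::modifyList(
    list(mean = 500, sd = 250, range_km = 12, coast_cor = 0.65), elevation_params)
  fp <- utils::modifyList(
    list(mean = 0.25, range_km = 7, steep = 3), forest_params)

  n_cols <- max(2L, round(extent_km[1] * 1000 / cell_size))
  n_rows <- max(2L, round(extent_km[2] * 1000 / cell_size))
  origin <- c(0, 0)
  coastline <- cbind(x = c(origin[1], origin[1]),
                     y = c(origin[2], origin[2] + n_rows * cell_size))

  xc <- origin[1] + (seq_len(n_cols) - 0.5) * cell_size
  yc <- origin[2] + (seq_len(n_rows) - 0.5) * cell_size
  dc <- matrix(rep(xc - origin[1], each = n_rows), n_rows, n_cols)

  withr::with_seed(seed, {
    zf <- smooth_gaussian_field(n_rows, n_cols, ep$range_km * 1000 / cell_size)
    zd <- if (sd(dc) > 0) (dc - mean(dc)) / sd(dc) else dc * 0
    if (sd(zd) > 0 && sd(zf) > 0) {
      # residualize the random field against the coast trend so the
      # configured elevation/coast correlation is hit in-sample
      zf <- zf - mean(zf * zd) / mean(zd * zd) * zd
      zf <- (zf - mean(zf)) / sd(zf)
    }
    a <- ep$coast_cor
    elev_z <- if (ep$sd > 0) a * zd + sqrt(max(0, 1 - a^2)) * zf else zd * 0
    elevation <- ep$mean + ep$sd * elev_z
    elevation[elevation < 0] <- 0
    zf2 <- smooth_gaussian_field(n_rows, n_cols, fp$range_km * 1000 / cell_size)
    forest <- stats::plogis(stats::qlogis(fp$mean) + fp$steep * zf2)
  })

  structure(
    list(origin = origin, cell_size = cell_size,
         n_cols = n_cols, n_rows = n_rows,
         elevation = elevation, forest_fraction = forest,
         coastline = coastline, seed = seed),
    class = "dsm_landscape")
}

# Standardized Gaussian random field: white noise smoothed with a separable
# Gaussian kernel (reflection padding), then rescaled to mean 0, sd 1.
smooth_gaussian_field <- function(n_rows, n_cols, sigma_cells) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma_cells > 0.3) {
    half <- max(1L, ceiling(3 * sigma_cells))
    kern <- stats::dnorm(seq(-half, half), sd = sigma_cells)
    kern <- kern / sum(kern)
    z <- apply(z, 2, conv_reflect, kern = kern)
    z <- t(apply(z, 1, conv_reflect, kern = kern))
  }
  if (sd(z) > 0) z <- (z - mean(z)) / sd(z)
  z
}

conv_reflect <- function(v, kern) {
  half <- (length(kern) - 1L) %/% 2L
  n <- length(v)
  padded <- c(v[pmin(n, (half + 1):2)], v, v[pmax(1, (n - 1):(n - half))])
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' @export
print.dsm_landscape <- function(x, ...) {
  cat("<dsm_landscape> ", x$n_cols, "x", x$n_rows, " cells of ",
      x$cell_size, " m (", round(x$n_cols * x$n_rows * (x$cell_size / 1000)^2),
      " km^2)\n", sep = "")
  cat("  elevation: ", round(min(x$elevation)), "-", round(max(x$elevation)),
      " m; forest fraction mean ", round(mean(x$forest_fraction), 2), "\n", sep = "")
  invisible(x)
}

#' Per-cell landscape table
#'
#' @param x A `dsm_landscape`.
#' @param ... Unused.
#' @return A tibble with one row per raster cell: cell-center coordinates,
#'   elevation, forest fraction, and distance to the coastline.
#' @method as_tibble dsm_landscape
#' @export
as_tibble.dsm_landscape <- function(x, ...) {
  xc <- x$origin[1] + (seq_len(x$n_cols) - 0.5) * x$cell_size
  yc <- x$origin[2] + (seq_len(x$n_rows) - 0.5) * x$cell_size
  g <- tidyr::expand_grid(col = seq_len(x$n_cols), row = seq_len(x$n_rows))
  px <- xc[g$col]
  py <- yc[g$row]
  elev <- x$elevation[cbind(g$row, g$col)]
  forest <- x$forest_fraction[cbind(g$row, g$col)]
  dc <- coast_distance(x, px, py)
  tibble::tibble(
    row = g$row, col = g$col, x = px, y = py,
    elevation = elev, forest_fraction = forest, distance_to_coast = dc)
}

#' Distance to the coastline
#'
#' Euclidean distance (m) from points to the landscape's coastline polyline;
#' always nonnegative.
#'
#' @param landscape A `dsm_landscape` (or any list with a `coastline` matrix).
#' @param x,y Point coordinates in meters.
#' @return Numeric vector of distances.
#' @export
coast_distance <- function(landscape, x, y) {
  dist_to_polyline(cbind(x, y), landscape$coastline)
}

# Nearest-cell raster lookup; points are clamped into the raster extent.
raster_lookup <- function(landscape, x, y, what = c("elevation", "forest_fraction")) {
  what <- match.arg(what)
  col <- pmin(landscape$n_cols, pmax(1L, ceiling((x - landscape$origin[1]) / landscape$cell_size)))
  row <- pmin(landscape$n_rows, pmax(1L, ceiling((y - landscape$origin[2]) / landscape$cell_size)))
  landscape[[what]][cbind(row, col)]
}

#' Lay out systematic strip transects
#'
#' Straight, evenly spaced parallel flight lines spanning the landscape.
#' The default east--west orientation runs perpendicular to the coastline,
#' so each transect crosses the coast-distance and elevation gradients —
#' the coverage a density-surface design needs to avoid spurious model
#' results.
#'
#' @param landscape A `dsm_landscape`.
#' @param n_transects Number of parallel transects.
#' @param margin_frac Fraction of the cross-transect extent left clear at
#'   each side before spacing the transects.
#' @param orientation `"EW"` (west to east, default) or `"NS"` (south to
#'   north).
#' @return A tibble of path vertices: `transect_id`, `x`, `y` (two vertices
#'   per transect).
#' @export
make_flight_paths <- function(landscape, n_transects = 12, margin_frac = 0.05,
                              orientation = c("EW", "NS")) {
  orientation <- match.arg(orientation)
  if (n_transects < 1) abort("`n_transects` must be >= 1.", class = "invalid_argument")
  w <- landscape$n_cols * landscape$cell_size
  h <- landscape$n_rows * landscape$cell_size
  across <- if (orientation == "EW") h else w
  a0 <- margin_frac * across
  a1 <- (1 - margin_frac) * across
  at <- if (n_transects == 1) (a0 + a1) / 2 else a0 + (seq_len(n_transects) - 0.5) * (a1 - a0) / n_transects
  ids <- rep(sprintf("T%02d", seq_len(n_transects)), each = 2)
  if (orientation == "EW") {
    tibble::tibble(transect_id = ids,
                   x = rep(c(landscape$origin[1], landscape$origin[1] + w), n_transects),
                   y = rep(landscape$origin[2] + at, each = 2))
  } else {
    tibble::tibble(transect_id = ids,
                   x = rep(landscape$origin[1] + at, each = 2),
                   y = rep(c(landscape$origin[2], landscape$origin[2] + h), n_transects))
  }
}
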