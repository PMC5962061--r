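# Prediction grid, abundance surfaces, and delta-method uncertainty.

#' Build the exclusion-filtered prediction grid
#'
#' Tiles the landscape with square cells of the configured area (default
#' 1.96 km^2, matching a full segment), anchored at the landscape origin;
#' partial edge cells are dropped so all cells share the same area. Cell
#' covariates are summarized exactly as for segments (dense sampling for
#' elevation and forest, centroid distance to coast), and cells at or above
#' the forest threshold are flagged excluded.
#'
#' @param landscape A `dsm_landscape`.
#' @param cell_area Cell area in km^2.
#' @param forest_threshold Exclusion threshold on forest fraction (>=).
#' @return A `dsm_grid` tibble: `cell_id`, `x`, `y`, `area_km2`,
#'   `mean_elevation`, `distance_to_coast`, `forest_fraction`, `excluded`;
#'   attribute `counts` holds total / excluded / retained.
#' @export
build_grid <- function(landscape, cell_area = 1.96, forest_threshold = 0.95) {
  if (cell_area <= 0) abort("`cell_area` must be > 0.", class = "invalid_argument")
  side <- sqrt(cell_area) * 1000
  w <- landscape$n_cols * landscape$cell_size
  h <- landscape$n_rows * landscape$cell_size
  nx <- floor(w / side + 1e-9)
  ny <- floor(h / side + 1e-9)
  if (nx < 1 || ny < 1) {
    abort("`cell_area` is larger than the landscape extent.", class = "invalid_argument")
  }
  g <- tidyr::expand_grid(iy = seq_len(ny), ix = seq_len(nx))
  cx <- landscape$origin[1] + (g$ix - 0.5) * side
  cy <- landscape$origin[2] + (g$iy - 0.5) * side
  # covariates via the same strip sampler used for segments: a cell is the
  # strip of a side-length centerline buffered by side/2
  half <- side / 2
  cov <- purrr::map2(cx, cy, function(x0, y0) {
    cl <- cbind(c(x0 - half, x0 + half), c(y0, y0))
    s <- strip_samples(cl, side, landscape$cell_size)
    c(elev = mean(raster_lookup(landscape, s[, 1], s[, 2], "elevation")),
      forest = mean(raster_lookup(landscape, s[, 1], s[, 2], "forest_fraction")))
  })
  grid <- tibble::tibble(
    cell_id = sprintf("C%05d", seq_along(cx)),
    x = cx, y = cy, area_km2 = cell_area,
    mean_elevation = vapply(cov, `[[`, numeric(1), "elev"),
    distance_to_coast = coast_distance(landscape, cx, cy),
    forest_fraction = vapply(cov, `[[`, numeric(1), "forest"))
  grid$excluded <- grid$forest_fraction >= forest_threshold
  if (all(grid$excluded)) {
    abort("Every grid cell is excluded by the forest rule; empty prediction grid.",
          class = "empty_grid")
  }
  attr(grid, "counts") <- c(total = nrow(grid),
                            excluded = sum(grid$excluded),
                            retained = sum(!grid$excluded))
  class(grid) <- c("dsm_grid", class(grid))
  grid
}

#' Predict per-cell abundance over a grid
#'
#' Evaluates the fitted log density per km^2 at each retained cell and
#' converts to expected abundance `N_c = exp(eta_c) * area_c`. Excluded
#' cells never appear in the output. Cells whose covariates fall outside
#' the range observed during fitting are flagged extrapolated, not clipped.
#'
#' @param fit A `dsm_fit`.
#' @param grid A `dsm_grid` from [build_grid()].
#' @return A `dsm_surface` tibble: `cell_id`, `x`, `y`, `area_km2`,
#'   `abundance`, `cv` (delta-method per-cell CV), `extrapolated`.
#' @export
predict_cells <- function(fit, grid) {
  cells <- grid[!grid$excluded, , drop = FALSE]
  if (nrow(cells) == 0) abort("No retained cells to predict on.", class = "empty_grid")
  pr <- predict(fit, cells, se_fit = TRUE)
  out <- tibble::tibble(
    cell_id = cells$cell_id, x = cells$x, y = cells$y,
    area_km2 = cells$area_km2,
    abundance = exp(pr$eta) * cells$area_km2,
    cv = pr$se_eta,
    extrapolated = pr$extrapolated)
  class(out) <- c("dsm_surface", class(out))
  out
}

#' Total abundance and mean density of a surface
#'
#' Adds up the per-cell expected abundances and divides by the summed cell
#' area to obtain the mean density in individuals per km^2.
#'
#' @param surface A `dsm_surface` (any data frame with `abundance` and
#'   `area_km2`).
#' @return A one-row tibble: `abundance`, `area_km2`, `density`.
#' @examples
#' s <- tibble::tibble(abundance = c(2, 3), area_km2 = c(1.96, 1.96))
#' total_abundance(s)
#' @export
total_abundance <- function(surface) {
  if (nrow(surface) < 1) abort("Need at least one cell.", class = "invalid_argument")
  N <- sum(surface$abundance)
  A <- sum(surface$area_km2)
  tibble::tibble(abundance = N, area_km2 = A, density = N / A)
}

#' Delta-method and simulation uncertainty of an abundance surface
#'
#' Per-cell: on the log link, `Var(N_c) ~ N_c^2 x_c' V x_c`, so the
#' per-cell CV is `sqrt(x_c' V x_c)` with V the conditional coefficient
#' covariance. Total: `Var(sum N_c) = a' Xp V Xp' a` with `a` the vector of
#' per-cell abundances, which retains the full covariance between cells.
#' `method = "posterior"` instead samples coefficients from their
#' conditional Gaussian (fixed seed) and reports empirical CVs; it serves
#' as a cross-check of the delta method.
#'
#' @param fit A `dsm_fit`.
#' @param grid A `dsm_grid`.
#' @param method `"delta"` or `"posterior"`.
#' @param nsim Number of posterior draws.
#' @param seed Seed for the posterior draws.
#' @return A list of class `dsm_uncertainty`: `cells` (tibble with
#'   `abundance`, `se`, `cv`, `extrapolated`) and `total` (one row:
#'   `abundance`, `se`, `cv`).
#' @export
dsm_uncertainty <- function(fit, grid, method = c("delta", "posterior"),
                            nsim = 10000, seed = 1L) {
  method <- match.arg(method)
  cells <- grid[!grid$excluded, , drop = FALSE]
  Xp <- design_at(fit$design, cells)
  eta <- drop(Xp %*% fit$coefficients)
  a <- exp(eta) * cells$area_km2
  V <- (fit$Vp + t(fit$Vp)) / 2
  pr <- predict(fit, cells, se_fit = FALSE)
  if (method == "delta") {
    se_eta <- sqrt(pmax(0, rowSums((Xp %*% V) * Xp)))
    cell_se <- a * se_eta
    v <- drop(crossprod(Xp, a))
    tot_var <- drop(t(v) %*% V %*% v)
    tot_se <- sqrt(max(0, tot_var))
    cells_out <- tibble::tibble(cell_id = cells$cell_id,
                                abundance = a, se = cell_se, cv = se_eta,
                                extrapolated = pr$extrapolated)
    total <- tibble::tibble(abundance = sum(a), se = tot_se, cv = tot_se / sum(a))
  } else {
    ev <- eigen(V, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(V))
    draws <- withr::with_seed(seed, matrix(rnorm(nsim * nrow(V)), nrow(V), nsim))
    etas <- Xp %*% (fit$coefficients + L %*% draws)
    Ns <- exp(etas) * cells$area_km2
    totals <- colSums(Ns)
    cell_mean <- rowMeans(Ns)
    cell_sd <- apply(Ns, 1, sd)
    cells_out <- tibble::tibble(cell_id = cells$cell_id,
                                abundance = a, se = cell_sd,
                                cv = cell_sd / cell_mean,
                                extrapolated = pr$extrapolated)
    total <- tibble::tibble(abundance = sum(a), se = sd(totals),
                            cv = sd(totals) / mean(totals))
  }
  structure(list(cells = cells_out, total = total, method = method),
            class = "dsm_uncertainty")
}

#' @export
print.dsm_uncertainty <- function(x, ...) {
  cat("<dsm_uncertainty> (", x$method, ") total = ",
      round(x$total$abundance), " (CV ", round(100 * x$total$cv, 1), "%)\n", sep = "")
  invisible(x)
}

#' @export
print.dsm_grid <- function(x, ...) {
  ct <- attr(x, "counts")
  cat("<dsm_grid> ", ct["total"], " cells (", ct["excluded"], " excluded, ",
      ct["retained"], " retained)\n", sep = "")
  NextMethod()
}
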