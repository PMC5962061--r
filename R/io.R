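# Readers and writers for the exchanged plain-text formats: ASCII-grid
# rasters, GeoJSON LineStrings, CSV tables, and the JSON model file.

#' Write / read an ASCII-grid raster
#'
#' Standard ESRI-style ASCII grid: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from the northern edge downward.
#'
#' @param mat Matrix with rows running south to north (as in a
#'   `dsm_landscape`).
#' @param path File path.
#' @param origin Lower-left corner (x, y) in meters.
#' @param cell_size Cell size in meters.
#' @return `read_ascii_grid` returns a list: `mat`, `origin`, `cell_size`.
#' @export
write_ascii_grid <- function(mat, path, origin = c(0, 0), cell_size = 1000) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
    paste("xllcorner", format(origin[1], scientific = FALSE)),
    paste("yllcorner", format(origin[2], scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    "NODATA_value -9999"), con)
  for (i in rev(seq_len(nrow(mat)))) {
    writeLines(paste(format(mat[i, ], digits = 10, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- stats::setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                          vapply(hdr, `[`, "", 1))
  body <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  mat <- do.call(rbind, rev(body))
  list(mat = mat, origin = unname(vals[c("xllcorner", "yllcorner")]),
       cell_size = unname(vals["cellsize"]))
}

#' Write / read flight paths or a coastline as GeoJSON LineStrings
#'
#' @param paths Tibble of vertices (`transect_id`, `x`, `y`).
#' @param path File path.
#' @return `read_paths_geojson` returns the vertex tibble.
#' @export
write_paths_geojson <- function(paths, path) {
  feats <- lapply(split(paths, paths$transect_id), function(p) {
    list(type = "Feature",
         properties = list(transect_id = p$transect_id[1]),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(p[, c("x", "y")], 1, as.numeric,
                                                    simplify = FALSE))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_paths_geojson
#' @export
read_paths_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  dplyr::bind_rows(lapply(gj$features, function(f) {
    cc <- do.call(rbind, lapply(f$geometry$coordinates, function(v)
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    tibble::tibble(transect_id = as.character(f$properties$transect_id),
                   x = cc[, 1], y = cc[, 2])
  }))
}

#' Write / read sighting records as CSV
#'
#' Columns `x`, `y`, `group_size` and optionally `t` (seconds) or an
#' ISO-8601 `timestamp`, used only for ordering.
#'
#' @param records Records tibble.
#' @param path File path.
#' @return `read_records_csv` returns the records tibble.
#' @export
write_records_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write the segment table as CSV
#'
#' Drops the geometry list-column; one row per segment with id, centroid,
#' effort, count, covariates and exclusion flag.
#'
#' @param segments Segment table.
#' @param path File path.
#' @export
write_segments_csv <- function(segments, path) {
  keep <- setdiff(names(segments), "centerline")
  readr::write_csv(as.data.frame(segments)[keep], path)
  invisible(path)
}

#' Serialize / restore a fitted model as a JSON model file
#'
#' Stores everything prediction needs: the model label, Tweedie power,
#' dispersion, coefficients, per-term kind, knots, standardization,
#' constraint matrices, smoothing parameters, REML score and deviance
#' explained. `read_dsm_model` rebuilds a `dsm_fit` whose predictions match
#' the original.
#'
#' @param fit A `dsm_fit`.
#' @param path File path.
#' @return `read_dsm_model` returns a `dsm_fit`.
#' @export
write_dsm_model <- function(fit, path) {
  terms_ser <- lapply(fit$design$terms, function(tm) {
    out <- list(kind = tm$kind, label = tm$label, k = tm$k,
                cols_data = tm$cols_data, col_idx = tm$col_idx,
                rank = tm$rank, logdet_S = tm$logdet_S,
                Z = tm$Z, S = tm$S)
    if (tm$kind == "cr") {
      out$knots <- tm$knots
    } else {
      out$knots <- tm$knots; out$center <- tm$center
      out$scale <- tm$scale; out$Zc <- tm$Zc; out$d <- tm$d
    }
    out
  })
  payload <- list(
    package = "stripdsm", format = 1L,
    label = fit$label, p = fit$p, phi = fit$phi, rho = fit$rho,
    coefficients = fit$coefficients, lambda = fit$lambda,
    k = fit$k, reml = fit$reml, edf = fit$edf, term_edf = fit$term_edf,
    deviance = fit$deviance, null_deviance = fit$null_deviance,
    deviance_explained = fit$deviance_explained, n = fit$n,
    Vp = fit$Vp, cov_ranges = fit$cov_ranges, terms = terms_ser)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_dsm_model
#' @export
read_dsm_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- lapply(pl$terms, function(tm) {
    tm$Z <- as.matrix(tm$Z); tm$S <- as.matrix(tm$S)
    if (tm$kind == "cr") {
      tm$knots <- as.numeric(tm$knots)
      tm$cr <- cr_setup(tm$knots)
    } else {
      tm$knots <- as.matrix(tm$knots)
      tm$Zc <- as.matrix(tm$Zc)
      tm$center <- as.numeric(tm$center); tm$scale <- as.numeric(tm$scale)
    }
    class(tm) <- "smooth_term"
    tm
  })
  cov_ranges <- lapply(pl$cov_ranges, as.matrix)
  structure(
    list(label = pl$label, coefficients = as.numeric(pl$coefficients),
         lambda = as.numeric(pl$lambda), k = unlist(pl$k),
         p = pl$p, phi = pl$phi, reml = pl$reml,
         deviance = pl$deviance, null_deviance = pl$null_deviance,
         deviance_explained = pl$deviance_explained,
         edf = pl$edf, term_edf = unlist(pl$term_edf),
         Vp = as.matrix(pl$Vp),
         design = list(terms = terms, label = pl$label),
         rho = pl$rho, n = pl$n, cov_ranges = cov_ranges,
         bandwidth = 1400),
    class = "dsm_fit")
}
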