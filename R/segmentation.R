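#' Cut flight paths into equal-effort segments
#'
#' Divides each transect into consecutive arc-length slices of length equal
#' to the strip bandwidth, so full segments are approximately square strips
#' (1400 m x 1400 m = 1.96 km^2 at the default bandwidth). A terminal
#' remainder shorter than `min_fraction * bandwidth` is dropped; otherwise
#' it is kept with its true length and proportionally smaller effort area,
#' which the model accommodates through the log-area offset.
#'
#' @param paths Tibble of path vertices: `transect_id`, `x`, `y` in meters,
#'   ordered along the flight line; optional `season` column is carried.
#' @param bandwidth Strip width in meters.
#' @param min_fraction Minimum kept fraction of a terminal remainder, in
#'   \[0, 1\].
#' @param season Optional season label applied to all segments.
#' @return A tibble of segments with class `dsm_segments`: `segment_id`,
#'   `transect_id`, `seg_idx` (0-based order along the transect), centroid
#'   `x`, `y`, `length_m`, `area_km2`, `season`, and a `centerline`
#'   list-column of vertex matrices. The bandwidth is kept as an attribute.
#' @export
segmentize_transects <- function(paths, bandwidth = 1400, min_fraction = 0.5,
                                 season = NULL) {
  if (bandwidth <= 0) abort("`bandwidth` must be > 0.", class = "invalid_argument")
  if (min_fraction < 0 || min_fraction > 1) {
    abort("`min_fraction` must lie in [0, 1].", class = "invalid_argument")
  }
  season <- season %||% (if ("season" %in% names(paths)) paths$season[1] else NA_character_)
  out <- lapply(split(paths, paths$transect_id), function(p) {
    pm <- as.matrix(p[order(seq_len(nrow(p))), c("x", "y")])
    L <- polyline_length(pm)
    if (nrow(pm) < 2 || L <= 0) {
      abort("Degenerate flight path: need at least two distinct vertices.",
            class = "invalid_argument")
    }
    n_full <- floor(L / bandwidth + 1e-9)
    rem <- L - n_full * bandwidth
    keep_rem <- rem > 1e-6 && rem >= min_fraction * bandwidth - 1e-9
    breaks <- bandwidth * seq_len(n_full)
    pieces <- split_polyline(pm, breaks[breaks < L - 1e-9])
    if (!keep_rem && rem > 1e-6) pieces <- pieces[seq_len(n_full)]
    lens <- vapply(pieces, polyline_length, numeric(1))
    mids <- t(vapply(seq_along(pieces), function(i)
      point_at_arclength(pieces[[i]], lens[i] / 2)[1, ], numeric(2)))
    tibble::tibble(
      transect_id = p$transect_id[1],
      seg_idx = seq_along(pieces) - 1L,
      x = mids[, 1], y = mids[, 2],
      length_m = lens,
      area_km2 = lens * bandwidth / 1e6,
      centerline = pieces)
  })
  seg <- dplyr::bind_rows(out)
  seg <- dplyr::mutate(seg,
    segment_id = paste0(.data$transect_id, "-", .data$seg_idx),
    season = season, .before = 1)
  seg <- dplyr::relocate(seg, "segment_id", "transect_id", "seg_idx")
  attr(seg, "bandwidth") <- bandwidth
  class(seg) <- c("dsm_segments", class(seg))
  seg
}

#' Assign sighting records to segments
#'
#' Each record is assigned to the segment whose strip rectangle (centerline
#' buffered by half the bandwidth, flat caps) contains it; its group size is
#' added to that segment's count. A record exactly on the along-track
#' boundary between consecutive segments goes to the lower order index.
#' Records outside every strip are returned in an `unassigned` attribute, so
#' that total group sizes are conserved:
#' sum(counts) + sum(unassigned sizes) = sum(record sizes).
#'
#' @param segments A `dsm_segments` tibble from [segmentize_transects()].
#' @param records Tibble with `x`, `y`, `group_size` (integer >= 1).
#' @param bandwidth Strip width in meters; defaults to the bandwidth the
#'   segments were built with.
#' @return `segments` with a `count` column; attribute `unassigned` holds
#'   the records that fell outside all strips.
#' @export
assign_records <- function(segments, records, bandwidth = NULL) {
  bandwidth <- bandwidth %||% attr(segments, "bandwidth")
  if (nrow(records) > 0 && any(records$group_size < 1 | records$group_size %% 1 != 0)) {
    abort("Records must carry integer group sizes >= 1.", class = "invalid_record")
  }
  segments$count <- 0L
  pts <- cbind(records$x, records$y)
  n <- nrow(records)
  best_d <- rep(Inf, n); best_tr <- rep(NA_character_, n); best_along <- rep(NA_real_, n)
  by_tr <- split(seq_len(nrow(segments)), segments$transect_id)
  for (tr in names(by_tr)) {
    rows <- by_tr[[tr]][order(segments$seg_idx[by_tr[[tr]]])]
    pm <- do.call(rbind, lapply(segments$centerline[rows], function(m) m[-nrow(m), , drop = FALSE]))
    last <- segments$centerline[[rows[length(rows)]]]
    pm <- rbind(pm, last[nrow(last), , drop = FALSE])
    if (n > 0) {
      pr <- project_on_polyline(pts, pm)
      upd <- pr$dist < best_d
      best_d[upd] <- pr$dist[upd]
      best_tr[upd] <- tr
      best_along[upd] <- pr$along[upd]
    }
  }
  inside <- which(best_d <= bandwidth / 2)
  assigned_row <- rep(NA_integer_, n)
  for (i in inside) {
    rows <- by_tr[[best_tr[i]]]
    rows <- rows[order(segments$seg_idx[rows])]
    ends <- cumsum(segments$length_m[rows])
    j <- which(best_along[i] <= ends + 1e-6)[1]
    if (!is.na(j)) assigned_row[i] <- rows[j]
  }
  ok <- which(!is.na(assigned_row))
  if (length(ok)) {
    add <- tapply(records$group_size[ok], assigned_row[ok], sum)
    segments$count[as.integer(names(add))] <- segments$count[as.integer(names(add))] + as.integer(add)
  }
  attr(segments, "unassigned") <- records[setdiff(seq_len(n), ok), , drop = FALSE]
  segments
}

#' Records that fell outside every strip
#' @param segments Output of [assign_records()].
#' @return Tibble of unassigned records.
#' @export
unassigned_records <- function(segments) {
  attr(segments, "unassigned") %||%
    tibble::tibble(x = numeric(), y = numeric(), group_size = integer())
}

#' Summarize landscape covariates over segments
#'
#' For each segment strip: `mean_elevation` is the area-weighted mean of
#' elevation over the strip (evaluated by dense regular sampling of the
#' strip rectangle at sub-cell resolution), `forest_fraction` the
#' area-weighted mean forest cover, and `distance_to_coast` the Euclidean
#' distance from the segment centroid to the nearest coastline point.
#' Segments at or above the forest threshold are flagged `excluded`, the
#' same rule applied to prediction-grid cells.
#'
#' @param segments A `dsm_segments` tibble.
#' @param landscape A `dsm_landscape`.
#' @param forest_threshold Exclusion threshold on forest fraction (>=).
#' @return `segments` with `mean_elevation`, `distance_to_coast`,
#'   `forest_fraction`, `excluded` columns.
#' @export
summarize_covariates <- function(segments, landscape, forest_threshold = 0.95) {
  bw <- attr(segments, "bandwidth") %||% 1400
  ext_x <- landscape$origin[1] + c(0, landscape$n_cols * landscape$cell_size)
  ext_y <- landscape$origin[2] + c(0, landscape$n_rows * landscape$cell_size)
  sums <- purrr::map(segments$centerline, function(cl) {
    s <- strip_samples(cl, bw, landscape$cell_size)
    if (!any(s[, 1] >= ext_x[1] & s[, 1] <= ext_x[2] &
             s[, 2] >= ext_y[1] & s[, 2] <= ext_y[2])) {
      abort("Segment strip lies fully outside the landscape.", class = "coverage_error")
    }
    c(elev = mean(raster_lookup(landscape, s[, 1], s[, 2], "elevation")),
      forest = mean(raster_lookup(landscape, s[, 1], s[, 2], "forest_fraction")))
  })
  segments$mean_elevation <- vapply(sums, `[[`, numeric(1), "elev")
  segments$forest_fraction <- vapply(sums, `[[`, numeric(1), "forest")
  segments$distance_to_coast <- coast_distance(landscape, segments$x, segments$y)
  segments$excluded <- segments$forest_fraction >= forest_threshold
  segments
}

# Regular lattice of sample points covering the strip rectangle around a
# centerline, at a spacing no coarser than half the raster resolution.
strip_samples <- function(centerline, bandwidth, cell_size) {
  out <- list()
  step <- max(1, cell_size / 2)
  half <- bandwidth / 2
  n_w <- max(5L, ceiling(bandwidth / step))
  offs <- seq(-half, half, length.out = n_w + 1)
  offs <- (offs[-1] + offs[-length(offs)]) / 2
  for (j in seq_len(nrow(centerline) - 1L)) {
    a <- centerline[j, ]; b <- centerline[j + 1L, ]
    len <- sqrt(sum((b - a)^2))
    if (len <= 0) next
    u <- (b - a) / len
    nv <- c(-u[2], u[1])
    n_a <- max(5L, ceiling(len / step))
    ts <- (seq_len(n_a) - 0.5) / n_a * len
    base <- cbind(a[1] + ts * u[1], a[2] + ts * u[2])
    for (o in offs) {
      out[[length(out) + 1L]] <- cbind(base[, 1] + o * nv[1], base[, 2] + o * nv[2])
    }
  }
  do.call(rbind, out)
}

#' Pearson collinearity screen between two covariates
#'
#' Computes the Pearson correlation between two covariate columns and flags
#' whether they must be placed in separate candidate models, using the
#' |r| >= threshold rule (default 0.4).
#'
#' @param data A data frame (typically the segment table).
#' @param x,y Unquoted column names.
#' @param threshold Absolute-correlation threshold.
#' @return A one-row tibble: `r`, `separate_models`.
#' @examples
#' collinearity_screen(data.frame(a = 1:10, b = (1:10)^2), a, b)
#' @export
collinearity_screen <- function(data, x, y, threshold = 0.4) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  if (length(xv) != length(yv) || length(xv) < 3) {
    abort("Need two equal-length vectors with at least 3 observations.",
          class = "invalid_argument")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Correlation undefined for a zero-variance covariate.",
          class = "undefined_correlation")
  }
  r <- cor(xv, yv)
  tibble::tibble(r = r, separate_models = abs(r) >= threshold)
}

#' Tally sighting records
#'
#' Survey bookkeeping: number of photographic records (rows) and total
#' individuals (summed group sizes), optionally by grouping columns such as
#' season or survey date.
#'
#' @param records Records tibble with `group_size`.
#' @param ... Unquoted grouping columns.
#' @return A tibble with `n_records` and `individuals` per group.
#' @export
tally_records <- function(records, ...) {
  dplyr::summarise(dplyr::group_by(records, ...),
                   n_records = dplyr::n(),
                   individuals = sum(.data$group_size),
                   .groups = "drop")
}
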