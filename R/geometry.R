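# Internal planar geometry on projected coordinates (meters).
# Polylines are matrices with columns x, y; all distances Euclidean.

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# Project points onto a polyline. For every point returns:
#   dist   - perpendicular distance to the nearest sub-segment whose
#            (unclamped) projection parameter lies in [0, 1]; Inf when the
#            point lies beyond the flat caps of every sub-segment
#   along  - arc-length position of that projection from the first vertex
#   dist_clamped - distance to the polyline with projections clamped to ends
# Flat caps: a point past the terminal vertex projects outside every
# sub-segment and gets dist = Inf even if the endpoint itself is close.
project_on_polyline <- function(pts, path) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  best_along <- rep(NA_real_, n)
  best_clamp <- rep(Inf, n)
  seg_len <- sqrt(rowSums(diff(path)^2))
  cum0 <- c(0, cumsum(seg_len))
  eps <- 1e-9
  for (j in seq_len(nrow(path) - 1L)) {
    if (seg_len[j] <= 0) next
    ax <- path[j, 1]; ay <- path[j, 2]
    dx <- path[j + 1L, 1] - ax; dy <- path[j + 1L, 2] - ay
    tt <- ((pts[, 1] - ax) * dx + (pts[, 2] - ay) * dy) / seg_len[j]^2
    tcl <- pmin(1, pmax(0, tt))
    ex <- pts[, 1] - (ax + tcl * dx)
    ey <- pts[, 2] - (ay + tcl * dy)
    dcl <- sqrt(ex^2 + ey^2)
    inside <- tt >= -eps & tt <= 1 + eps
    upd <- inside & dcl < best
    if (any(upd)) {
      best[upd] <- dcl[upd]
      best_along[upd] <- cum0[j] + tcl[upd] * seg_len[j]
    }
    best_clamp <- pmin(best_clamp, dcl)
  }
  list(dist = best, along = best_along, dist_clamped = best_clamp)
}

# Minimum distance from points to a polyline (projections clamped to ends).
dist_to_polyline <- function(pts, path) {
  project_on_polyline(pts, path)$dist_clamped
}

# Interpolate the point at arc-length s along a polyline.
point_at_arclength <- function(path, s) {
  seg_len <- sqrt(rowSums(diff(path)^2))
  cum0 <- c(0, cumsum(seg_len))
  s <- pmin(max(cum0), pmax(0, s))
  out <- matrix(NA_real_, length(s), 2)
  for (i in seq_along(s)) {
    j <- max(1L, findInterval(s[i], cum0, rightmost.closed = TRUE))
    j <- min(j, length(seg_len))
    f <- if (seg_len[j] > 0) (s[i] - cum0[j]) / seg_len[j] else 0
    out[i, ] <- path[j, ] + f * (path[j + 1L, ] - path[j, ])
  }
  out
}

# Cut a polyline at arc lengths `breaks` (sorted, within [0, L]);
# returns list of vertex matrices, one per piece.
split_polyline <- function(path, breaks) {
  L <- polyline_length(path)
  breaks <- sort(unique(pmin(L, pmax(0, breaks))))
  bounds <- unique(c(0, breaks, L))
  pieces <- vector("list", length(bounds) - 1L)
  seg_len <- sqrt(rowSums(diff(path)^2))
  cum0 <- c(0, cumsum(seg_len))
  for (i in seq_along(pieces)) {
    s0 <- bounds[i]; s1 <- bounds[i + 1L]
    inner <- which(cum0 > s0 + 1e-9 & cum0 < s1 - 1e-9)
    verts <- rbind(point_at_arclength(path, s0),
                   path[inner, , drop = FALSE],
                   point_at_arclength(path, s1))
    pieces[[i]] <- verts
  }
  pieces
}
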