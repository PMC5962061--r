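# Spline bases and quadratic roughness penalties.
#
# Univariate smooths use a cubic regression spline in the value-second
# derivative parameterization: coefficients are the function values at k
# knots placed at data quantiles, natural boundary conditions tie the
# second derivatives, and the penalty is the exact integrated squared
# second derivative. Bivariate (and trivariate) smooths use a knot-based
# thin-plate radial basis on standardized coordinates with the bending
# energy of the radial part as penalty. All smooths are centered by a
# sum-to-zero constraint over the fitting data, absorbed by a QR null-space
# reparameterization.

#' Build a univariate cubic-spline smooth term
#'
#' Constructs a cubic regression spline basis of dimension `k` with knots at
#' data quantiles, the exact second-derivative roughness penalty, and the
#' sum-to-zero identifiability constraint absorbed into the design. The
#' penalty null space (constant + linear) means a straight line is never
#' penalized; outside the knot range the spline continues linearly.
#'
#' @param values Covariate values (need at least `k` distinct values).
#' @param k Basis dimension, between 4 and 20.
#' @param label Term label used in reports.
#' @return A `smooth_term` list: constrained design matrix `X` (k - 1
#'   columns, each summing to ~0 over the data), penalty `S` (PSD), knots,
#'   constraint basis, and evaluation metadata.
#' @export
build_univariate_smooth <- function(values, k = 10, label = deparse(substitute(values))) {
  if (k < 4 || k > 20) abort("`k` must lie in [4, 20].", class = "invalid_argument")
  ux <- unique(values)
  if (length(ux) < k) {
    abort(sprintf("Need at least k = %d distinct covariate values.", k),
          class = "rank_error")
  }
  knots <- as.numeric(quantile(ux, probs = seq(0, 1, length.out = k), type = 7))
  knots <- sort(knots)
  if (any(diff(knots) <= 0)) {
    # fall back to evenly spread distinct values when quantiles coincide
    knots <- sort(ux)[round(seq(1, length(ux), length.out = k))]
  }
  cr <- cr_setup(knots)
  X <- cr_design(values, cr)
  term <- list(kind = "cr", label = label, vars = label, k = k,
               knots = knots, cr = cr, S_raw = cr$S,
               range = range(values))
  absorb_constraint(term, X)
}

# Natural cubic spline setup (value-based parameterization).
# D maps knot values to scaled second differences, B is the tridiagonal
# mass matrix of the second-derivative interpolation; Fm = B^{-1} D maps
# values to second derivatives at interior knots (zeros at the ends), and
# S = D' B^{-1} D is the integrated squared second derivative.
cr_setup <- function(knots) {
  k <- length(knots)
  h <- diff(knots)
  D <- matrix(0, k - 2, k)
  B <- matrix(0, k - 2, k - 2)
  for (i in seq_len(k - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) {
      B[i, i + 1] <- h[i + 1] / 6
      B[i + 1, i] <- h[i + 1] / 6
    }
  }
  Fi <- solve(B, D)
  Fm <- rbind(0, Fi, 0)          # k x k: second derivatives at all knots
  S <- crossprod(D, Fi)          # D' B^{-1} D
  S <- (S + t(S)) / 2
  list(knots = knots, h = h, Fm = Fm, S = S)
}

# Evaluate the unconstrained cubic spline design at x (linear extrapolation
# beyond the boundary knots).
cr_design <- function(x, cr) {
  knots <- cr$knots; h <- cr$h; Fm <- cr$Fm
  k <- length(knots)
  X <- matrix(0, length(x), k)
  inb <- x >= knots[1] & x <= knots[k]
  j <- pmin(k - 1L, pmax(1L, findInterval(x, knots, all.inside = TRUE)))
  for (i in which(inb)) {
    jj <- j[i]; hj <- h[jj]
    am <- (knots[jj + 1] - x[i]) / hj
    ap <- (x[i] - knots[jj]) / hj
    cm <- ((knots[jj + 1] - x[i])^3 / hj - hj * (knots[jj + 1] - x[i])) / 6
    cp <- ((x[i] - knots[jj])^3 / hj - hj * (x[i] - knots[jj])) / 6
    row <- cm * Fm[jj, ] + cp * Fm[jj + 1, ]
    row[jj] <- row[jj] + am
    row[jj + 1] <- row[jj + 1] + ap
    X[i, ] <- row
  }
  if (any(!inb)) {
    # f and f' at the boundary knots, then linear continuation
    dl <- -h[1] / 6 * Fm[2, ]; dl[1] <- dl[1] - 1 / h[1]; dl[2] <- dl[2] + 1 / h[1]
    dr <- h[k - 1] / 6 * Fm[k - 1, ]
    dr[k - 1] <- dr[k - 1] - 1 / h[k - 1]; dr[k] <- dr[k] + 1 / h[k - 1]
    for (i in which(!inb)) {
      if (x[i] < knots[1]) {
        row <- numeric(k); row[1] <- 1
        X[i, ] <- row + (x[i] - knots[1]) * dl
      } else {
        row <- numeric(k); row[k] <- 1
        X[i, ] <- row + (x[i] - knots[k]) * dr
      }
    }
  }
  X
}

#' Build a thin-plate-style radial smooth of location (and optionally a
#' third input)
#'
#' Isotropic radial basis on standardized coordinates: `k` knots are chosen
#' by deterministic farthest-point selection among the data sites; the
#' design combines the polynomial null space (intercept + linear terms)
#' with radial functions (`r^2 log r` in 2-D, `-r` in 3-D) whose
#' coefficients are constrained orthogonal to the polynomials, and the
#' penalty is the radial bending energy. A plane is in the penalty null
#' space and is never penalized; the basis is invariant to 90-degree
#' rotations of the coordinates (standardization is per input).
#'
#' @param coords Matrix or data frame of 2 (x, y) or 3 (x, y, covariate)
#'   columns.
#' @param k Basis dimension, at most 20 and at least the null-space
#'   dimension + 2.
#' @param label Term label.
#' @return A `smooth_term` list as in [build_univariate_smooth()]; the
#'   constrained design has k - 1 columns and the penalty null-space
#'   dimension is `ncol(coords)` after the sum-to-zero constraint.
#' @export
build_location_smooth <- function(coords, k = 20, label = "location") {
  coords <- as.matrix(coords)
  d <- ncol(coords)
  if (!d %in% c(2L, 3L)) abort("`coords` must have 2 or 3 columns.", class = "invalid_argument")
  if (k > 20) abort("`k` must be <= 20.", class = "invalid_argument")
  if (k < d + 3) abort(sprintf("`k` must be at least %d for a %d-input smooth.", d + 3, d),
                       class = "invalid_argument")
  keep <- !duplicated(coords)
  uc <- coords[keep, , drop = FALSE]
  if (nrow(uc) < k) abort("Need at least `k` distinct sites.", class = "rank_error")
  ctr <- colMeans(coords)
  scl <- apply(coords, 2, sd)
  if (any(scl == 0) || qr(sweep(coords, 2, ctr))$rank < d) {
    abort("Sites are collinear/degenerate; cannot build a surface smooth.",
          class = "rank_error")
  }
  z <- sweep(sweep(coords, 2, ctr), 2, scl, "/")
  zu <- sweep(sweep(uc, 2, ctr), 2, scl, "/")
  kn <- zu[farthest_points(zu, k), , drop = FALSE]

  Tk <- cbind(1, kn)                       # polynomials at knots, k x (d+1)
  Ek <- radial_eval(kn, kn, d)
  Zc <- qr.Q(qr(Tk), complete = TRUE)[, -(seq_len(d + 1)), drop = FALSE]
  S_rad <- crossprod(Zc, Ek %*% Zc)
  S_rad <- (S_rad + t(S_rad)) / 2
  p <- ncol(Zc) + d + 1                    # total = k columns
  S <- matrix(0, p, p)
  S[seq_len(ncol(Zc)) + d + 1, seq_len(ncol(Zc)) + d + 1] <- S_rad
  X <- cbind(1, z, radial_eval(z, kn, d) %*% Zc)
  term <- list(kind = "tp", label = label, vars = label, k = k, d = d,
               knots = kn, center = ctr, scale = scl, Zc = Zc, S_raw = S,
               range = apply(coords, 2, range))
  absorb_constraint(term, X)
}

# Radial basis function matrix eta(|a_i - b_j|): r^2 log r (2-D, the thin
# plate spline kernel) or -r (3-D).
radial_eval <- function(a, b, d) {
  r2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  r2[r2 < 0] <- 0
  if (d == 2) {
    out <- 0.5 * r2 * log(pmax(r2, 1e-300))
    out[r2 == 0] <- 0
    out
  } else {
    -sqrt(r2)
  }
}

# Deterministic farthest-point knot selection: start at the site nearest
# the centroid, then greedily add the site farthest from those chosen.
farthest_points <- function(z, k) {
  n <- nrow(z)
  ctr <- colMeans(z)
  sel <- integer(k)
  sel[1] <- which.min(rowSums(sweep(z, 2, ctr)^2))
  mind <- rowSums(sweep(z, 2, z[sel[1], ])^2)
  for (i in seq_len(k - 1L)) {
    sel[i + 1L] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(z, 2, z[sel[i + 1L], ])^2))
  }
  sel
}

# Absorb the sum-to-zero constraint over the data into the term: the
# constrained design columns sum to zero and the penalty is projected
# accordingly. Stores what prediction needs to rebuild rows.
absorb_constraint <- function(term, X) {
  cvec <- colSums(X)
  Zc <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  term$Z <- Zc
  term$X <- X %*% Zc
  S <- crossprod(Zc, term$S_raw %*% Zc)
  term$S <- (S + t(S)) / 2
  ev <- eigen(term$S, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(ev) * 1e-9
  term$rank <- sum(ev > tol)
  term$logdet_S <- sum(log(ev[ev > tol]))
  term$null_dim <- ncol(term$X) - term$rank
  class(term) <- "smooth_term"
  term
}

# Evaluate a term's constrained design at new covariate data.
eval_smooth <- function(term, newdata_mat) {
  X <- if (term$kind == "cr") {
    cr_design(newdata_mat[, 1], term$cr)
  } else {
    z <- sweep(sweep(as.matrix(newdata_mat), 2, term$center), 2, term$scale, "/")
    cbind(1, z, radial_eval(z, term$knots, term$d) %*% term$Zc)
  }
  X %*% term$Z
}

#' @export
print.smooth_term <- function(x, ...) {
  cat("<smooth_term> ", x$label, " (", x$kind, "), k = ", x$k,
      ", penalty rank ", x$rank, "\n", sep = "")
  invisible(x)
}
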