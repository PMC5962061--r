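# Penalized Tweedie regression with log link and effort-area offset.
#
# The linear predictor is eta = X beta + log(area), so the intercept is on
# the log density-per-km^2 scale. Coefficients minimize
#   tweedie_deviance(y, exp(eta), p) + sum_j lambda_j * beta' S_j beta
# by penalized IRLS; smoothing parameters minimize a Laplace-approximate
# negative restricted marginal likelihood (REML), with the dispersion
# profiled out.

# ---- model specs ----------------------------------------------------------

# Candidate labels follow the field shorthand: AA = average altitude
# (mean_elevation), DC = distance to coast, GL = geographic location (x, y);
# "AA+GL" is additive, "AA:GL" a joint 3-input radial smooth, "1" intercept
# only.
term_catalog <- function() {
  list(
    AA = list(kind = "cr", cols = "mean_elevation", k = 10),
    DC = list(kind = "cr", cols = "distance_to_coast", k = 10),
    GL = list(kind = "tp", cols = c("x", "y"), k = 20),
    `AA:GL` = list(kind = "tp", cols = c("x", "y", "mean_elevation"), k = 15),
    `DC:GL` = list(kind = "tp", cols = c("x", "y", "distance_to_coast"), k = 15))
}

parse_model_label <- function(label) {
  label <- gsub(" ", "", label)
  if (label %in% c("1", "")) return(character())
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  known <- names(term_catalog())
  bad <- setdiff(parts, known)
  if (length(bad)) {
    abort(paste0("Unknown model terms: ", paste(bad, collapse = ", "),
                 ". Known: ", paste(known, collapse = ", "), " (or \"1\")."),
          class = "invalid_argument")
  }
  parts
}

# Build the full design for a model label on a segment table.
build_design <- function(segments, label, k = NULL) {
  parts <- parse_model_label(label)
  cat_ <- term_catalog()
  terms <- list()
  X <- matrix(1, nrow(segments), 1)
  colnames(X) <- "(Intercept)"
  col_at <- 1L
  for (nm in parts) {
    info <- cat_[[nm]]
    kk <- if (!is.null(k) && !is.null(k[[nm]])) k[[nm]] else info$k
    tm <- if (info$kind == "cr") {
      build_univariate_smooth(segments[[info$cols]], k = kk, label = nm)
    } else {
      build_location_smooth(as.matrix(segments[info$cols]), k = kk, label = nm)
    }
    tm$cols_data <- info$cols
    tm$col_idx <- col_at + seq_len(ncol(tm$X))
    terms[[nm]] <- tm
    X <- cbind(X, tm$X)
    col_at <- col_at + ncol(tm$X)
  }
  list(X = X, terms = terms, label = label)
}

design_at <- function(design, newdata) {
  X <- matrix(1, nrow(newdata), 1)
  for (tm in design$terms) {
    X <- cbind(X, eval_smooth(tm, as.matrix(newdata[tm$cols_data])))
  }
  X
}

# ---- penalized IRLS -------------------------------------------------------

penalized_irls <- function(X, y, offset, terms, lambda, p,
                           rho = 0, transect = NULL, order_idx = NULL,
                           tol = 1e-8, maxit = 200) {
  n <- nrow(X); P <- ncol(X)
  if (sum(y) <= 0) {
    abort("Total count is zero; the log-link intercept is unbounded.",
          class = "invalid_argument")
  }
  S_lam <- matrix(0, P, P)
  for (j in seq_along(terms)) {
    idx <- terms[[j]]$col_idx
    S_lam[idx, idx] <- S_lam[idx, idx] + lambda[j] * terms[[j]]$S
  }
  mu <- pmax(y, mean(y) / 10) + mean(y) / 10
  eta <- log(mu)
  beta <- NULL
  dev_pen_old <- Inf
  for (it in seq_len(maxit)) {
    w <- mu^(2 - p)
    z <- (eta - offset) + (y - mu) / mu
    sw <- sqrt(w)
    A <- X * sw
    u <- sw * z
    if (rho != 0) {
      ord <- order(transect, order_idx)
      A_o <- A[ord, , drop = FALSE]; u_o <- u[ord]
      tr <- transect[ord]; oi <- order_idx[ord]
      nn <- length(u_o)
      run1 <- c(TRUE, tr[-1] != tr[-nn] | oi[-1] != (oi[-nn] + 1))
      s <- sqrt(1 - rho^2)
      lag <- which(!run1)
      A_w <- A_o; u_w <- u_o
      if (length(lag)) {
        A_w[lag, ] <- (A_o[lag, , drop = FALSE] - rho * A_o[lag - 1L, , drop = FALSE]) / s
        u_w[lag] <- (u_o[lag] - rho * u_o[lag - 1L]) / s
      }
      A <- A_w; u <- u_w
    }
    H <- crossprod(A) + S_lam
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) {
      # exact aliasing between unpenalized directions (e.g. a linear
      # covariate that coincides with a coordinate of the location smooth):
      # resolve with a minimal ridge so the fit is defined
      eps <- 1e-8 * mean(diag(H))
      ch <- tryCatch(chol(H + eps * diag(P)), error = function(e)
        abort("Penalized Hessian is singular.", class = "numerical_error"))
    }
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(A, u)))
    eta <- drop(X %*% beta) + offset
    eta <- pmin(eta, 35)
    mu <- exp(eta)
    dev <- tweedie_deviance(y, mu, p)
    dev_pen <- dev + drop(t(beta) %*% S_lam %*% beta)
    if (is.finite(dev_pen_old) &&
        abs(dev_pen_old - dev_pen) < tol * (abs(dev_pen) + 0.1)) {
      return(list(beta = drop(beta), mu = mu, eta = eta, deviance = dev,
                  dev_pen = dev_pen, H = H, chol_H = ch, A = A,
                  XtWX = crossprod(A), S_lam = S_lam, iter = it, converged = TRUE))
    }
    dev_pen_old <- dev_pen
  }
  abort(sprintf("Penalized IRLS did not converge in %d iterations (last penalized deviance %.6g).",
                maxit, dev_pen_old), class = "convergence_error")
}

# Laplace-approximate negative restricted log likelihood (lower is better),
# using the deviance-based Gaussian approximation at the penalized optimum
# with the dispersion profiled as phi = dev_pen / (n - M), M = total
# penalty null-space dimension (unpenalized coefficients).
reml_from_fit <- function(fitobj, terms, lambda, n) {
  P <- ncol(fitobj$XtWX)
  ranks <- vapply(terms, `[[`, numeric(1), "rank")
  M <- P - sum(ranks)
  phi <- fitobj$dev_pen / max(1, n - M)
  ldet_H <- 2 * sum(log(diag(fitobj$chol_H)))
  ldet_S <- sum(ranks * log(lambda)) +
    sum(vapply(terms, `[[`, numeric(1), "logdet_S"))
  0.5 * ((n - M) * (1 + log(2 * pi * phi)) + ldet_H - ldet_S)
}

#' REML score of a candidate smoothing-parameter vector
#'
#' Fits the penalized model at fixed smoothing parameters and returns the
#' Laplace-approximate negative restricted marginal likelihood used for
#' smoothing selection (lower is better). Exposed mainly for diagnostics
#' and tests; [fit_dsm()] minimizes this internally.
#'
#' @param segments Segment table with counts, areas and covariates.
#' @param model Model label (e.g. `"AA+GL"`).
#' @param lambda Positive smoothing parameters, one per term.
#' @param p Tweedie power.
#' @param k Optional named list of basis dimensions per term.
#' @return The REML score (numeric scalar).
#' @export
reml_score <- function(segments, model, lambda, p = 1.5, k = NULL) {
  seg <- prepare_segments(segments)
  des <- build_design(seg, model, k = k)
  f <- penalized_irls(des$X, seg$count, log(seg$area_km2), des$terms, lambda, p)
  reml_from_fit(f, des$terms, lambda, nrow(seg))
}

prepare_segments <- function(segments) {
  req <- c("count", "area_km2")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols)) {
    abort(paste0("Segment table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "schema_error")
  }
  seg <- segments
  if ("excluded" %in% names(seg)) seg <- seg[!seg$excluded, , drop = FALSE]
  if (any(seg$area_km2 <= 0)) abort("Segment areas must be positive.", class = "invalid_argument")
  seg
}

# ---- user-facing fit ------------------------------------------------------

#' Fit a density surface model to segment counts
#'
#' Penalized-spline regression of per-segment counts on environmental
#' covariates with a Tweedie response, log link and `log(area_km2)` offset,
#' so the intercept is on the log individuals-per-km^2 scale. Smoothing
#' parameters are selected by minimizing a Laplace-approximate REML score
#' (deterministic log-scale multistart followed by derivative-free polish);
#' optionally the basis dimension of each term is chosen over a grid within
#' k = 4-20 by the same criterion. Excluded segments (forest rule) are
#' dropped before fitting.
#'
#' @param segments Segment table (see [summarize_covariates()]); needs
#'   `count`, `area_km2` and the covariates the model uses.
#' @param model Model label: `"AA"`, `"DC"`, `"GL"`, `"AA+GL"`, `"DC+GL"`,
#'   `"AA:GL"`, `"DC:GL"` or `"1"` (intercept only). AA = mean elevation,
#'   DC = distance to coast, GL = geographic location.
#' @param p Tweedie power in (1, 2); `p = 1` fits the Poisson boundary.
#' @param k Optional named list of basis dimensions per term (defaults:
#'   10 for univariate, 20 for GL, 15 for joint smooths).
#' @param lambda Optional fixed smoothing parameters (skips REML search).
#' @param select_k If `TRUE`, greedily search `k_grid` per term by REML.
#' @param k_grid Candidate basis dimensions for `select_k`.
#' @param rho AR(1) working correlation between consecutive segments within
#'   a transect (0 = independent working model).
#' @param profile_p If `TRUE`, profile the Tweedie power over
#'   `seq(1.1, 1.9, by = 0.1)` by the REML-type score.
#' @return A `dsm_fit` object; see [tidy.dsm_fit()] and [glance.dsm_fit()].
#' @export
fit_dsm <- function(segments, model = "AA+GL", p = 1.5, k = NULL,
                    lambda = NULL, select_k = FALSE,
                    k_grid = c(4, 8, 12, 16, 20), rho = 0,
                    profile_p = FALSE) {
  seg <- prepare_segments(segments)
  transect <- if ("transect_id" %in% names(seg)) seg$transect_id else rep("T", nrow(seg))
  order_idx <- if ("seg_idx" %in% names(seg)) seg$seg_idx else seq_len(nrow(seg))
  if (profile_p) {
    grid_p <- seq(1.1, 1.9, by = 0.1)
    fits <- lapply(grid_p, function(pp)
      fit_dsm(seg, model, p = pp, k = k, lambda = lambda,
              select_k = FALSE, rho = rho))
    scores <- vapply(fits, function(f) f$reml, numeric(1))
    best <- fits[[which.min(scores)]]
    best$p_profile <- tibble::tibble(p = grid_p, reml = scores)
    return(best)
  }

  parts <- parse_model_label(model)
  k_used <- k
  if (select_k && length(parts)) {
    k_used <- if (is.null(k)) list() else k
    for (nm in parts) {
      if (is.null(k_used[[nm]])) k_used[[nm]] <- term_catalog()[[nm]]$k
    }
    for (nm in parts) {
      cand <- k_grid[k_grid >= 4 & k_grid <= 20]
      if (term_catalog()[[nm]]$kind == "tp") {
        dmin <- length(term_catalog()[[nm]]$cols) + 3
        cand <- cand[cand >= dmin]
      }
      scores <- vapply(cand, function(kk) {
        kt <- k_used; kt[[nm]] <- kk
        ft <- try(fit_dsm_core(seg, model, p, kt, lambda, rho, transect, order_idx),
                  silent = TRUE)
        if (inherits(ft, "try-error")) Inf else ft$reml
      }, numeric(1))
      k_used[[nm]] <- cand[which.min(scores)]
    }
  }
  fit_dsm_core(seg, model, p, k_used, lambda, rho, transect, order_idx)
}

fit_dsm_core <- function(seg, model, p, k, lambda, rho, transect, order_idx) {
  des <- build_design(seg, model, k = k)
  y <- seg$count
  offset <- log(seg$area_km2)
  n <- nrow(seg)
  J <- length(des$terms)

  do_fit <- function(lam) {
    penalized_irls(des$X, y, offset, des$terms, lam, p,
                   rho = rho, transect = transect, order_idx = order_idx)
  }

  if (J == 0) {
    f <- do_fit(numeric())
    lam <- numeric()
  } else if (!is.null(lambda)) {
    lam <- rep_len(lambda, J)
    f <- do_fit(lam)
  } else {
    score_log <- function(ll) {
      ft <- try(do_fit(exp(ll)), silent = TRUE)
      if (inherits(ft, "try-error")) return(1e10)
      reml_from_fit(ft, des$terms, exp(ll), n)
    }
    starts <- log(10^seq(-3, 6, length.out = 7))
    s0 <- vapply(starts, function(s) score_log(rep(s, J)), numeric(1))
    init <- rep(starts[which.min(s0)], J)
    opt <- if (J == 1) {
      optim(init, score_log, method = "Brent", lower = log(1e-8), upper = log(1e12))
    } else {
      optim(init, score_log, method = "Nelder-Mead",
            control = list(maxit = 400, reltol = 1e-7))
    }
    lam <- exp(opt$par)
    f <- do_fit(lam)
  }

  # dispersion from the Pearson statistic; edf from the influence trace
  Hi <- chol2inv(f$chol_H)
  edf_mat <- Hi %*% f$XtWX
  edf <- sum(diag(edf_mat))
  phi <- sum((y - f$mu)^2 / f$mu^p) / max(1, n - edf)
  Vp <- phi * Hi
  reml <- reml_from_fit(f, des$terms, lam, n)

  null_dev <- null_deviance(y, offset, p)
  dev_expl <- if (null_dev > 0) 100 * (null_dev - f$deviance) / null_dev else NA_real_

  term_edf <- vapply(des$terms, function(tm) sum(diag(edf_mat)[tm$col_idx]), numeric(1))
  cov_ranges <- lapply(des$terms, function(tm) {
    apply(as.matrix(seg[tm$cols_data]), 2, range)
  })

  structure(
    list(label = model, coefficients = f$beta, lambda = lam,
         k = vapply(des$terms, `[[`, numeric(1), "k"),
         p = p, phi = phi, reml = reml,
         deviance = f$deviance, null_deviance = null_dev,
         deviance_explained = dev_expl,
         edf = edf, term_edf = term_edf, Vp = Vp,
         design = des, rho = rho,
         n = n, y = y, mu = f$mu, offset = offset,
         transect = transect, order_idx = order_idx,
         bandwidth = attr(seg, "bandwidth") %||% 1400,
         cov_ranges = cov_ranges, iter = f$iter),
    class = "dsm_fit")
}

null_deviance <- function(y, offset, p) {
  # intercept + offset only: one-parameter fit by direct search
  f <- function(b) tweedie_deviance(y, exp(pmin(b + offset, 35)), p)
  opt <- optimize(f, interval = log(sum(y) / sum(exp(offset))) + c(-4, 4))
  opt$objective
}

#' Percent deviance explained relative to the intercept + offset model
#'
#' @param fit A `dsm_fit`.
#' @return `100 * (D_null - D_model) / D_null` at the fitted Tweedie power.
#' @export
deviance_explained <- function(fit) fit$deviance_explained

#' Predict the linear predictor at new covariate values
#'
#' Evaluates the fitted smooths at new data (no offset: the result is the
#' log density per km^2). Values of a covariate outside the range observed
#' during fitting are flagged as extrapolation.
#'
#' @param object A `dsm_fit`.
#' @param newdata Data frame with the covariates the model uses.
#' @param se_fit If `TRUE`, include the delta-method standard error of the
#'   linear predictor.
#' @param ... Unused.
#' @return A tibble: `eta` (log density per km^2), optional `se_eta`,
#'   and `extrapolated`.
#' @export
predict.dsm_fit <- function(object, newdata, se_fit = FALSE, ...) {
  miss <- setdiff(unique(unlist(lapply(object$design$terms, `[[`, "cols_data"))),
                  names(newdata))
  if (length(miss)) {
    abort(paste0("Covariate(s) missing from `newdata`: ", paste(miss, collapse = ", ")),
          class = "schema_error")
  }
  X <- design_at(object$design, newdata)
  eta <- drop(X %*% object$coefficients)
  extrap <- rep(FALSE, nrow(newdata))
  for (tm in object$design$terms) {
    rng <- object$cov_ranges[[tm$label]]
    for (j in seq_along(tm$cols_data)) {
      v <- newdata[[tm$cols_data[j]]]
      extrap <- extrap | v < rng[1, j] - 1e-9 | v > rng[2, j] + 1e-9
    }
  }
  out <- tibble::tibble(eta = eta, extrapolated = extrap)
  if (se_fit) {
    out$se_eta <- sqrt(pmax(0, rowSums((X %*% object$Vp) * X)))
  }
  out
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat("<dsm_fit> ", x$label, " | Tweedie p = ", x$p,
      ", phi = ", signif(x$phi, 3), "\n", sep = "")
  cat("  n = ", x$n, ", edf = ", round(x$edf, 2),
      ", REML = ", round(x$reml, 2),
      ", deviance explained = ", round(x$deviance_explained, 1), "%\n", sep = "")
  if (x$rho != 0) cat("  AR(1) working correlation rho = ", round(x$rho, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_dsm
#' @param x,object A `dsm_fit`.
#' @param ... Unused.
#' @method tidy dsm_fit
#' @export
tidy.dsm_fit <- function(x, ...) {
  if (length(x$design$terms) == 0) {
    return(tibble::tibble(term = character(), k = integer(), edf = numeric(),
                          lambda = numeric(), statistic = numeric(),
                          p.value = numeric()))
  }
  stats_ <- vapply(names(x$design$terms), function(nm)
    term_wald(x, nm), numeric(2))
  tibble::tibble(
    term = names(x$design$terms),
    k = as.integer(x$k),
    edf = as.numeric(x$term_edf),
    lambda = as.numeric(x$lambda),
    statistic = stats_[1, ],
    p.value = stats_[2, ])
}

# Wald-type test of a smooth term: quadratic form of its coefficients in
# the pseudo-inverse of their covariance block, referred to chi^2 with
# df = term edf (rounded up to at least 1).
term_wald <- function(fit, term_name) {
  tm <- fit$design$terms[[term_name]]
  b <- fit$coefficients[tm$col_idx]
  V <- fit$Vp[tm$col_idx, tm$col_idx, drop = FALSE]
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  # drop only (near-)null directions, judged against the typical eigenvalue:
  # an aliased direction with huge variance must stay, since its ~zero
  # precision removes it from the statistic through 1/value
  scale_ev <- stats::median(ev$values[ev$values > 0])
  pos <- ev$values > scale_ev * 1e-12
  Vinv <- ev$vectors[, pos, drop = FALSE] %*%
    (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  stat <- drop(t(b) %*% Vinv %*% b)
  df <- max(1, fit$term_edf[[term_name]])
  c(stat, pchisq(stat, df = df, lower.tail = FALSE))
}

#' @rdname fit_dsm
#' @method glance dsm_fit
#' @export
glance.dsm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$label, n = x$n, p = x$p, phi = x$phi, rho = x$rho,
    edf = x$edf, reml = x$reml,
    deviance = x$deviance, null_deviance = x$null_deviance,
    deviance_explained = x$deviance_explained)
}
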