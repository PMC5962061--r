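# Candidate-set model selection by REML, residual autocorrelation
# diagnostics along transects, and AR(1)-corrected refitting.

#' Fit and rank a candidate model set
#'
#' Fits every candidate model on the same segment table and ranks them by
#' the REML score (ascending; lowest is best). The default candidate set is
#' the seven structures combining average elevation (AA), distance to coast
#' (DC) and geographic location (GL) additively or as joint smooths.
#'
#' @param segments Segment table with counts, areas and covariates.
#' @param candidates Character vector of model labels.
#' @param ... Passed to [fit_dsm()] (e.g. `p`, `select_k`, `k`).
#' @return A `dsm_candidates` tibble: `model`, `deviance_explained`,
#'   `reml`, `edf`, `k` (list-column of chosen basis dimensions), sorted by
#'   REML; the fitted objects are kept in the `fits` attribute.
#' @export
run_candidates <- function(segments,
                           candidates = c("AA+GL", "DC+GL", "GL",
                                          "AA:GL", "DC:GL", "AA", "DC"),
                           ...) {
  if (length(candidates) < 1) abort("Need at least one candidate.", class = "invalid_argument")
  if (anyDuplicated(candidates)) abort("Candidate labels must be unique.", class = "invalid_argument")
  fits <- list(); errs <- list()
  for (cand in candidates) {
    f <- try(fit_dsm(segments, model = cand, ...), silent = TRUE)
    if (inherits(f, "try-error")) errs[[cand]] <- conditionMessage(attr(f, "condition"))
    else fits[[cand]] <- f
  }
  if (length(fits) == 0) {
    abort(paste0("All candidates failed:\n",
                 paste(names(errs), unlist(errs), sep = ": ", collapse = "\n")),
          class = "selection_error")
  }
  tbl <- dplyr::bind_rows(lapply(fits, function(f)
    tibble::tibble(model = f$label,
                   deviance_explained = f$deviance_explained,
                   reml = f$reml, edf = f$edf,
                   k = list(f$k))))
  tbl <- dplyr::arrange(tbl, .data$reml, .data$edf)
  attr(tbl, "fits") <- fits
  attr(tbl, "errors") <- errs
  class(tbl) <- c("dsm_candidates", class(tbl))
  tbl
}

#' Select the best candidate by lowest REML
#'
#' Works on a [run_candidates()] table or any data frame with `model` and
#' `reml` columns (e.g. a published score table). Ties within 1e-10 are
#' broken by fewer effective degrees of freedom when an `edf` column is
#' present.
#'
#' @param candidate_table Data frame with `model` and `reml`.
#' @return The winning model label (character scalar).
#' @export
select_best <- function(candidate_table) {
  if (!all(c("model", "reml") %in% names(candidate_table))) {
    abort("`candidate_table` needs `model` and `reml` columns.", class = "schema_error")
  }
  tbl <- candidate_table
  best_reml <- min(tbl$reml)
  tied <- tbl[tbl$reml <= best_reml + 1e-10, , drop = FALSE]
  if (nrow(tied) > 1 && "edf" %in% names(tied)) {
    tied <- tied[order(tied$edf), , drop = FALSE]
  }
  tied$model[1]
}

#' Best fitted model from a candidate table
#' @param candidate_table A `dsm_candidates` table carrying fitted objects.
#' @return The `dsm_fit` of the best candidate.
#' @export
best_fit <- function(candidate_table) {
  fits <- attr(candidate_table, "fits")
  if (is.null(fits)) abort("No fitted objects attached to this table.", class = "invalid_argument")
  fits[[select_best(candidate_table)]]
}

# Pooled within-transect lag correlation of a series: pairs (i, i + lag)
# whose order indices are exactly `lag` apart inside the same transect,
# pooled across transects, Pearson correlation.
pooled_lag_cor <- function(values, transect, order_idx, lag = 1L) {
  ord <- order(transect, order_idx)
  v <- values[ord]; tr <- transect[ord]; oi <- order_idx[ord]
  n <- length(v)
  if (n <= lag) return(NA_real_)
  i <- seq_len(n - lag)
  ok <- tr[i] == tr[i + lag] & (oi[i + lag] - oi[i]) == lag
  if (sum(ok) < 3) return(NA_real_)
  cor(v[i][ok], v[i + lag][ok])
}

#' Residual autocorrelation along transects
#'
#' Correlates deviance residuals of adjacent segments within transects
#' (lag 1 = one segment length apart, lag 2 = two segment lengths), pooled
#' across transects, and applies the correction trigger: correction is
#' required when any lag correlation exceeds 0.15.
#'
#' @param fit A `dsm_fit`.
#' @param lags Integer lags to report.
#' @return A `dsm_acf` tibble: `lag`, `distance_m`, `correlation`;
#'   attribute `triggered` per the > 0.15 rule (also via [acf_triggered()]).
#' @export
residual_acf <- function(fit, lags = 1:2) {
  tab <- table(fit$transect)
  if (all(tab < 3)) {
    abort("All transects have fewer than 3 segments; autocorrelation undefined.",
          class = "insufficient_data")
  }
  r <- tweedie_dev_resid(fit$y, fit$mu, fit$p)
  cors <- vapply(lags, function(l) pooled_lag_cor(r, fit$transect, fit$order_idx, l),
                 numeric(1))
  out <- tibble::tibble(lag = as.integer(lags),
                        distance_m = as.numeric(lags) * fit$bandwidth,
                        correlation = cors)
  attr(out, "triggered") <- any(!is.na(cors) & cors > 0.15)
  attr(out, "threshold") <- 0.15
  class(out) <- c("dsm_acf", class(out))
  out
}

#' Did the autocorrelation report trigger correction?
#' @param acf_report A `dsm_acf` from [residual_acf()].
#' @return Logical: any lag correlation > 0.15.
#' @export
acf_triggered <- function(acf_report) isTRUE(attr(acf_report, "triggered"))

#' Refit with an AR(1) working correlation within transects
#'
#' Refits the penalized model whitening consecutive segments within each
#' transect by the AR(1) transform (the additive-model analogue of a GAMM
#' with within-transect AR(1) errors). With `rho = "estimate"` the working
#' correlation is taken from the lag-1 pooled correlation of deviance
#' residuals and iterated to convergence (at most 10 iterations).
#' Smoothing parameters are re-optimized by default.
#'
#' @param segments Segment table.
#' @param model Model label.
#' @param rho `"estimate"` or a fixed value in (-1, 1).
#' @param ... Passed to [fit_dsm()].
#' @return A `dsm_fit` with the working correlation in `$rho`.
#' @export
fit_ar1 <- function(segments, model, rho = "estimate", ...) {
  if (is.numeric(rho)) {
    if (abs(rho) >= 1) abort("`rho` must satisfy |rho| < 1.", class = "invalid_argument")
    return(fit_dsm(segments, model = model, rho = rho, ...))
  }
  rho_cur <- 0
  fit <- fit_dsm(segments, model = model, rho = 0, ...)
  for (it in seq_len(10)) {
    r <- tweedie_dev_resid(fit$y, fit$mu, fit$p)
    rho_new <- pooled_lag_cor(r, fit$transect, fit$order_idx, 1L)
    if (is.na(rho_new)) {
      abort("Cannot estimate rho: too few adjacent segment pairs.",
            class = "insufficient_data")
    }
    rho_new <- max(-0.95, min(0.95, rho_new))
    if (abs(rho_new - rho_cur) < 1e-3) { rho_cur <- rho_new; break }
    rho_cur <- rho_new
    fit <- fit_dsm(segments, model = model, rho = rho_cur, ...)
  }
  fit$rho <- rho_cur
  fit
}

#' Drop non-significant smooth terms and refit
#'
#' Applies a Wald-type test to each smooth term (coefficients against their
#' conditional covariance); while the least significant term has p >= alpha
#' the term is removed and the model refitted. Mirrors the elimination of a
#' term that loses significance after autocorrelation correction.
#'
#' @param fit A `dsm_fit`.
#' @param segments The segment table the fit used.
#' @param alpha Significance level.
#' @param ... Passed to [fit_dsm()] on refits (e.g. `rho`).
#' @return A `dsm_fit`, possibly with fewer terms; dropped labels in
#'   `$dropped_terms`.
#' @export
prune_terms <- function(fit, segments, alpha = 0.05, ...) {
  dropped <- character()
  cur <- fit
  repeat {
    td <- tidy(cur)
    if (nrow(td) == 0) break
    worst <- td[which.max(td$p.value), ]
    if (worst$p.value < alpha) break
    dropped <- c(dropped, worst$term)
    remaining <- setdiff(td$term, dropped)
    new_label <- if (length(remaining)) paste(remaining, collapse = "+") else "1"
    cur <- fit_dsm(segments, model = new_label, p = fit$p, ...)
  }
  cur$dropped_terms <- dropped
  cur
}

#' Compare an independence fit with its AR(1)-corrected counterpart
#'
#' Reports, for both fits, the total predicted abundance over a grid and
#' its delta-method coefficient of variation, plus the largest absolute
#' coefficient difference when the two fits share a model structure. A
#' report, not a decision.
#'
#' @param fit_gam Independence (`rho = 0`) fit.
#' @param fit_gamm AR(1)-corrected fit.
#' @param grid Prediction grid from [build_grid()].
#' @return Tibble with one row per fit: `model`, `rho`, `abundance`,
#'   `cv`; attribute `max_coef_diff`.
#' @export
compare_gam_gamm <- function(fit_gam, fit_gamm, grid) {
  row_for <- function(f) {
    u <- dsm_uncertainty(f, grid)
    tibble::tibble(model = f$label, rho = f$rho,
                   abundance = u$total$abundance, cv = u$total$cv)
  }
  out <- dplyr::bind_rows(row_for(fit_gam), row_for(fit_gamm))
  same <- identical(fit_gam$label, fit_gamm$label) &&
    length(fit_gam$coefficients) == length(fit_gamm$coefficients)
  attr(out, "max_coef_diff") <- if (same) {
    max(abs(fit_gam$coefficients - fit_gamm$coefficients))
  } else NA_real_
  out
}

#' @export
print.dsm_candidates <- function(x, ...) {
  cat("<dsm_candidates> ", nrow(x), " models, best = ", select_best(x), "\n", sep = "")
  NextMethod()
}
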