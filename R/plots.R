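# ggplot2 visualizations of fitted smooths, abundance surfaces, and
# autocorrelation reports.

#' Plot the estimated smooth terms of a fitted model
#'
#' Univariate smooths are drawn as the centered effect on the log-density
#' scale with approximate 95% pointwise bands; the geographic-location
#' smooth is drawn as a filled surface over the data's bounding box.
#'
#' @param object A `dsm_fit`.
#' @param n_grid Evaluation points per axis.
#' @param ... Unused.
#' @return A ggplot (patchworked list if several terms; the first term's
#'   plot when patchwork is unavailable).
#' @method autoplot dsm_fit
#' @export
autoplot.dsm_fit <- function(object, n_grid = 100, ...) {
  plots <- lapply(names(object$design$terms), function(nm) {
    tm <- object$design$terms[[nm]]
    rng <- object$cov_ranges[[nm]]
    idx <- tm$col_idx
    b <- object$coefficients[idx]
    V <- object$Vp[idx, idx, drop = FALSE]
    if (tm$kind == "cr") {
      xg <- seq(rng[1, 1], rng[2, 1], length.out = n_grid)
      Xg <- eval_smooth(tm, matrix(xg, ncol = 1))
      f <- drop(Xg %*% b)
      se <- sqrt(pmax(0, rowSums((Xg %*% V) * Xg)))
      df <- tibble::tibble(x = xg, f = f, lo = f - 1.96 * se, hi = f + 1.96 * se)
      ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$f)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.25) +
        ggplot2::geom_line() +
        ggplot2::labs(x = tm$cols_data, y = paste0("s(", nm, ", ",
                      round(object$term_edf[[nm]], 1), ")")) +
        ggplot2::theme_minimal()
    } else {
      g <- tidyr::expand_grid(
        x = seq(rng[1, 1], rng[2, 1], length.out = n_grid),
        y = seq(rng[1, 2], rng[2, 2], length.out = n_grid))
      M <- as.matrix(g)
      if (tm$d == 3) M <- cbind(M, mean(rng[, 3]))
      f <- drop(eval_smooth(tm, M) %*% b)
      df <- dplyr::mutate(g, f = f)
      ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$f)) +
        ggplot2::geom_raster() +
        ggplot2::scale_fill_viridis_c(name = paste0("s(", nm, ")")) +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
        ggplot2::theme_minimal()
    }
  })
  if (length(plots) == 0) {
    abort("Intercept-only fit: no smooth terms to plot.", class = "invalid_argument")
  }
  if (length(plots) > 1 && requireNamespace("patchwork", quietly = TRUE)) {
    return(patchwork::wrap_plots(plots))
  }
  plots[[1]]
}

#' Map an abundance surface
#'
#' @param object A `dsm_surface` from [predict_cells()].
#' @param what `"abundance"` or `"cv"`.
#' @param ... Unused.
#' @return A ggplot raster map.
#' @method autoplot dsm_surface
#' @export
autoplot.dsm_surface <- function(object, what = c("abundance", "cv"), ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
}

#' Plot a residual autocorrelation report
#'
#' Bars of the pooled within-transect lag correlations with the 0.15
#' correction trigger drawn as a dashed line.
#'
#' @param object A `dsm_acf`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dsm_acf
#' @export
autoplot.dsm_acf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$distance_m), y = .data$correlation)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold") %||% 0.15,
                        linetype = "dashed") +
    ggplot2::labs(x = "Lag distance (m)", y = "Residual correlation") +
    ggplot2::theme_minimal()
}

#' @rdname residual_acf
#' @param x A `dsm_acf`.
#' @param ... Unused.
#' @method tidy dsm_acf
#' @export
tidy.dsm_acf <- function(x, ...) {
  tibble::tibble(lag = x$lag, distance_m = x$distance_m,
                 correlation = x$correlation,
                 triggered = acf_triggered(x))
}

#' @rdname run_candidates
#' @param x A `dsm_candidates` table.
#' @param ... Unused.
#' @method tidy dsm_candidates
#' @export
tidy.dsm_candidates <- function(x, ...) {
  tibble::tibble(model = x$model,
                 deviance_explained = x$deviance_explained,
                 reml = x$reml, edf = x$edf,
                 rank = seq_len(nrow(x)),
                 best = x$model == select_best(x))
}
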