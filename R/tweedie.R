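#' Tweedie deviance
#'
#' Total deviance of nonnegative observations under a Tweedie family with
#' power `p`. For `1 < p < 2` the unit deviance is
#' `2 * (y^(2-p) / ((1-p)(2-p)) - y * mu^(1-p) / (1-p) + mu^(2-p) / (2-p))`;
#' the boundaries are the Poisson (`p = 1`) and gamma (`p = 2`) deviances,
#' which the compound Poisson-gamma deviance approaches in the limit. The
#' unit deviance is nonnegative and zero exactly when `y = mu`.
#'
#' @param y Nonnegative observations (counts or totals).
#' @param mu Strictly positive means.
#' @param p Tweedie power in \[1, 2\].
#' @param total If `FALSE`, return per-observation unit deviances.
#' @return Total (or per-observation) deviance.
#' @examples
#' tweedie_deviance(c(0, 3, 5), c(1, 3, 2), p = 1.5)
#' @export
tweedie_deviance <- function(y, mu, p = 1.5, total = TRUE) {
  if (any(mu <= 0)) abort("`mu` must be strictly positive.", class = "invalid_argument")
  if (any(y < 0)) abort("`y` must be nonnegative.", class = "invalid_argument")
  if (p < 1 || p > 2) abort("`p` must lie in [1, 2].", class = "invalid_argument")
  if (p == 1) {
    d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  } else if (p == 2) {
    if (any(y <= 0)) abort("Gamma deviance needs y > 0.", class = "invalid_argument")
    d <- 2 * ((y - mu) / mu - log(y / mu))
  } else {
    ypow <- ifelse(y > 0, y^(2 - p), 0)
    d <- 2 * (ypow / ((1 - p) * (2 - p)) - y * mu^(1 - p) / (1 - p) + mu^(2 - p) / (2 - p))
  }
  d <- pmax(d, 0)
  if (total) sum(d) else d
}

# Deviance residuals for a Tweedie fit.
tweedie_dev_resid <- function(y, mu, p) {
  sign(y - mu) * sqrt(tweedie_deviance(y, mu, p, total = FALSE))
}
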