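test_that("Tweedie deviance matches its boundary families", {
  # d(0, mu) = 2 mu^(2-p) / (2-p): zero observations contribute through mu only
  expect_equal(tweedie_deviance(c(0, 3, 7), c(1, 3, 7), p = 1.5), 4)
  expect_equal(tweedie_deviance(0, 2, 1.5), 2 * 2^0.5 / 0.5)
  expect_equal(tweedie_deviance(3, 3, 1.5), 0)
  # p -> 1: Poisson unit deviance 2 * (y log(y/mu) - (y - mu))
  expect_equal(tweedie_deviance(2, 1, 1 + 1e-6), 2 * (2 * log(2) - 1),
               tolerance = 1e-4)
  # p -> 2: gamma unit deviance 2 * ((y - mu)/mu - log(y/mu))
  expect_equal(tweedie_deviance(2, 1, 2 - 1e-6), 2 * (1 - log(2)),
               tolerance = 1e-4)
  expect_gt(tweedie_deviance(4, 2, 1.3), 0)
  expect_error(tweedie_deviance(1, 0, 1.5), class = "invalid_argument")
  expect_error(tweedie_deviance(1, 1, 2.5), class = "invalid_argument")
})

test_that("unpenalized fits match brute-force deviance minimization", {
  seg <- toy_segments(20, seed = 42)
  seg$area_km2 <- withr::with_seed(43, runif(20, 0.8, 1.2))
  fit <- fit_dsm(seg, "AA", p = 1.5, k = list(AA = 4), lambda = 0)
  des <- stripdsm:::build_design(seg, "AA", k = list(AA = 4))
  obj <- function(b) tweedie_deviance(seg$count,
                                      exp(pmin(des$X %*% b + log(seg$area_km2), 30)), 1.5)
  o <- optim(rep(0, ncol(des$X)), obj, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(max(abs(o$par - fit$coefficients)), 1e-5)
})

test_that("the p = 1 boundary reproduces penalized Poisson IRLS", {
  seg <- toy_segments(50, seed = 7)
  fit <- fit_dsm(seg, "AA", p = 1, k = list(AA = 5), lambda = 0)
  des <- stripdsm:::build_design(seg, "AA", k = list(AA = 5))
  gl <- glm(seg$count ~ des$X - 1 + offset(log(seg$area_km2)), family = poisson())
  expect_lt(max(abs(unname(coef(gl)) - fit$coefficients)), 1e-6)
})

test_that("doubling effort areas shifts only the intercept by -log(2)", {
  seg <- toy_segments(30, seed = 11)
  f1 <- fit_dsm(seg, "AA", k = list(AA = 5), lambda = 2)
  f2 <- fit_dsm(dplyr::mutate(seg, area_km2 = 2 * area_km2), "AA",
                k = list(AA = 5), lambda = 2)
  expect_equal(f2$coefficients[1] - f1$coefficients[1], -log(2), tolerance = 1e-7)
  expect_lt(max(abs(f2$coefficients[-1] - f1$coefficients[-1])), 1e-7)
})

test_that("a huge penalty collapses the smooth to its null space", {
  # the second-derivative penalty leaves constant + linear unpenalized, so
  # lambda -> infinity approaches the Tweedie fit with a linear covariate
  seg <- toy_segments(60, seed = 13, mu = 8)
  fbig <- fit_dsm(seg, "AA", k = list(AA = 8), lambda = 1e12)
  Xlin <- cbind(1, seg$mean_elevation)
  obj <- function(b) tweedie_deviance(seg$count,
                                      pmax(exp(pmin(Xlin %*% b, 30)), 1e-12), 1.5)
  o <- optim(c(log(mean(seg$count)), 0), obj, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  eta_lin <- drop(Xlin %*% o$par)
  eta_fit <- log(fbig$mu) - fbig$offset
  expect_lt(max(abs(eta_fit - eta_lin)), 1e-4)
})

test_that("total count of zero is rejected", {
  seg <- toy_segments(10, seed = 1)
  seg$count <- 0L
  expect_error(fit_dsm(seg, "AA", k = list(AA = 4)), class = "invalid_argument")
})

test_that("the REML score is invariant to segment order", {
  seg <- toy_segments(40, seed = 21)
  s1 <- reml_score(seg, "AA", lambda = 3, k = list(AA = 6))
  s2 <- reml_score(seg[withr::with_seed(1, sample(40)), ], "AA",
                   lambda = 3, k = list(AA = 6))
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("pure-noise smooths are shrunk to the largest candidate lambda", {
  wins <- 0
  grid <- 10^c(-2, 0, 2, 4, 6)
  for (r in 1:50) {
    seg <- toy_segments(100, seed = 300 + r)
    sc <- vapply(grid, function(l) reml_score(seg, "AA", l, k = list(AA = 6)),
                 numeric(1))
    if (which.min(sc) == length(grid)) wins <- wins + 1
  }
  expect_gte(wins, 45)  # >= 90% of 50 replicates
})

test_that("REML-selected smoothing beats both extremes out of sample", {
  gen <- function(seed) withr::with_seed(seed, {
    xx <- runif(300, 0, 1000)
    tibble::tibble(count = rpois(300, exp(1 + 2 * sin(xx / 1000 * 2 * pi))),
                   area_km2 = 1, mean_elevation = xx,
                   transect_id = "T", seg_idx = seq_len(300))
  })
  tr <- gen(31); te <- gen(32)
  ood <- function(f) tweedie_deviance(te$count, exp(predict(f, te)$eta), 1.5)
  fsel <- fit_dsm(tr, "AA", k = list(AA = 20))
  f0 <- fit_dsm(tr, "AA", k = list(AA = 20), lambda = 0)
  fbig <- fit_dsm(tr, "AA", k = list(AA = 20), lambda = 1e8)
  expect_lt(ood(fsel), ood(f0))
  expect_lt(ood(fsel), ood(fbig))
})

test_that("intercept-only specs skip smoothing and conserve the mean", {
  seg <- toy_segments(25, seed = 3)
  f <- fit_dsm(seg, "1")
  expect_length(f$lambda, 0)
  expect_equal(sum(f$mu), sum(seg$count), tolerance = 1e-6)
})

test_that("deviance explained is the documented deviance ratio", {
  st <- demo_study()
  f <- fit_dsm(st$segments, "AA")
  expect_equal(f$deviance_explained,
               100 * (f$null_deviance - f$deviance) / f$null_deviance)
  expect_gte(f$deviance_explained, 0)
  expect_lte(f$deviance_explained, 100)
  f0 <- fit_dsm(st$segments, "1")
  expect_equal(f0$deviance_explained, 0, tolerance = 1e-4)
})

test_that("effective degrees of freedom stay within the basis budget", {
  st <- demo_study()
  f <- fit_dsm(st$segments, "AA+GL")
  expect_true(all(f$term_edf <= f$k - 1 + 1e-6))
  expect_true(all(f$mu > 0))
  td <- tidy(f)
  expect_setequal(td$term, c("AA", "GL"))
  expect_true(all(td$lambda > 0))
  g <- glance(f)
  expect_equal(g$n, sum(!st$segments$excluded))
})

test_that("basis-dimension search respects the configured maximum", {
  seg <- toy_segments(90, seed = 17, mu = 6)
  f <- fit_dsm(seg, "AA", select_k = TRUE, k_grid = c(4, 8, 20))
  expect_lte(unname(f$k["AA"]), 20)
  expect_gte(unname(f$k["AA"]), 4)
})

test_that("fits agree with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  st <- demo_study()
  seg <- st$segments[!st$segments$excluded, ]
  ours <- fit_dsm(st$segments, "AA")
  ref <- mgcv::gam(count ~ s(mean_elevation, k = 10, bs = "cr") +
                     offset(log(area_km2)),
                   family = mgcv::Tweedie(p = 1.5, link = "log"),
                   data = seg, method = "REML")
  expect_gt(cor(ours$mu, fitted(ref)), 0.98)
  expect_lt(abs(sum(ours$mu) - sum(fitted(ref))) / sum(fitted(ref)), 0.02)
})

test_that("fitted smooths recover a known quadratic effect", {
  # pooled pointwise coverage of approximate 95% bands across replicates
  covered <- 0; total <- 0
  for (r in 1:20) {
    seg <- withr::with_seed(500 + r, {
      e <- runif(150, 0, 1000)
      eff <- -1.5 * ((e - 500) / 500)^2
      tibble::tibble(count = rpois(150, exp(1.5 + eff)), area_km2 = 1,
                     mean_elevation = e, transect_id = "T", seg_idx = 1:150)
    })
    f <- fit_dsm(seg, "AA")
    tm <- f$design$terms$AA; idx <- tm$col_idx
    eg <- seq(quantile(seg$mean_elevation, 0.02),
              quantile(seg$mean_elevation, 0.98), length.out = 40)
    Xg <- stripdsm:::eval_smooth(tm, matrix(eg, ncol = 1))
    fhat <- drop(Xg %*% f$coefficients[idx])
    se <- sqrt(pmax(0, rowSums((Xg %*% f$Vp[idx, idx]) * Xg)))
    ftrue <- -1.5 * ((eg - 500) / 500)^2
    ftrue <- ftrue - mean(-1.5 * ((seg$mean_elevation - 500) / 500)^2)
    covered <- covered + sum(abs(fhat - ftrue) <= 1.96 * se)
    total <- total + length(eg)
  }
  expect_gte(covered / total, 0.9)
})
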