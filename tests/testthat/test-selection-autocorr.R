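# AR(1) segment series on the log scale with Tweedie-like counts; large
# means keep sampling noise small relative to the link-scale noise.
ar1_segments <- function(seed, rho = 0.4, n_transects = 10, n_per = 100, sd = 0.5) {
  withr::with_seed(seed, {
    e <- if (rho == 0) rnorm(n_transects * n_per, 0, sd) else
      as.vector(replicate(n_transects,
        as.numeric(stats::arima.sim(list(ar = rho), n_per, sd = sd * sqrt(1 - rho^2)))))
    tibble::tibble(
      count = rpois(n_transects * n_per, exp(4 + e)),
      area_km2 = 1,
      transect_id = rep(sprintf("T%02d", seq_len(n_transects)), each = n_per),
      seg_idx = rep(seq_len(n_per), n_transects))
  })
}

test_that("published-style score tables select the lowest-REML model", {
  non_breeding <- tibble::tibble(
    model = c("AA+GL", "DC+GL", "GL", "DC:GL", "AA:GL", "AA", "DC"),
    reml = c(1091.30, 1099.70, 1101.80, 1102.10, 1103.10, 1109.90, 1125.70))
  breeding <- tibble::tibble(
    model = c("DC+GL", "AA+GL", "GL", "AA:GL", "DC:GL", "AA", "DC"),
    reml = c(1232.30, 1233.90, 1235.80, 1242.90, 1245.90, 1247.40, 1253.30))
  expect_equal(select_best(non_breeding), "AA+GL")
  expect_equal(select_best(breeding), "DC+GL")
  # selection is invariant to row order
  expect_equal(select_best(non_breeding[sample(7), ]), "AA+GL")
})

test_that("ties are broken by fewer effective degrees of freedom", {
  tbl <- tibble::tibble(model = c("A", "B"), reml = c(10, 10), edf = c(5, 3))
  expect_equal(select_best(tbl), "B")
  expect_equal(select_best(tibble::tibble(model = "only", reml = 1)), "only")
})

test_that("candidate tables are ranked by REML with fits attached", {
  st <- demo_study()
  tbl <- run_candidates(st$segments, candidates = c("AA", "DC", "1"))
  expect_equal(tbl$reml, sort(tbl$reml))
  expect_equal(select_best(tbl), tbl$model[1])
  bf <- best_fit(tbl)
  expect_s3_class(bf, "dsm_fit")
  expect_equal(bf$label, tbl$model[1])
  td <- tidy(tbl)
  expect_equal(sum(td$best), 1)
  expect_error(run_candidates(st$segments, candidates = c("AA", "AA")),
               class = "invalid_argument")
})

test_that("pooled lag correlations behave as white noise and AR(1) oracles", {
  withr::with_seed(1, {
    tr <- rep(sprintf("T%d", 1:5), each = 100)
    oi <- rep(1:100, 5)
    white <- rnorm(500)
  })
  expect_lt(abs(stripdsm:::pooled_lag_cor(white, tr, oi, 1)), 0.1)
  withr::with_seed(2, {
    tr2 <- rep("T", 1000); oi2 <- 1:1000
    ar <- as.numeric(stats::arima.sim(list(ar = 0.5), 1000))
  })
  expect_lt(abs(stripdsm:::pooled_lag_cor(ar, tr2, oi2, 1) - 0.5), 0.07)
  # pairs never cross transect boundaries: per-transect constants show no lag pairs
  v <- c(1, 2, 1, 2); expect_true(is.na(
    stripdsm:::pooled_lag_cor(v, c("a", "a", "b", "b"), c(1, 2, 1, 2), 2)))
})

test_that("the correction trigger fires exactly above 0.15", {
  seg_ar <- ar1_segments(3, rho = 0.4)
  f_ar <- fit_dsm(seg_ar, "1")
  rep_ar <- residual_acf(f_ar)
  expect_equal(acf_triggered(rep_ar), any(rep_ar$correlation > 0.15))
  expect_true(acf_triggered(rep_ar))     # simulated lag-1 ~ 0.35
  expect_equal(rep_ar$distance_m, c(1400, 2800))

  seg_iid <- ar1_segments(4, rho = 0)
  rep_iid <- residual_acf(fit_dsm(seg_iid, "1"))
  expect_equal(acf_triggered(rep_iid), any(rep_iid$correlation > 0.15))
  expect_false(acf_triggered(rep_iid))
  expect_true(all(abs(rep_iid$correlation) <= 1))
  expect_equal(tidy(rep_iid)$triggered, rep(FALSE, 2))
})

test_that("autocorrelation needs transects with at least 3 segments", {
  seg <- toy_segments(4, seed = 1, n_transects = 2)
  f <- fit_dsm(seg, "1")
  expect_error(residual_acf(f), class = "insufficient_data")
})

test_that("AR(1) whitening with rho = 0 is a no-op", {
  st <- demo_study()
  f0 <- fit_dsm(st$segments, "AA", lambda = 5)
  f1 <- fit_dsm(st$segments, "AA", lambda = 5, rho = 0)
  expect_lt(max(abs(f0$coefficients - f1$coefficients)), 1e-8)
  f2 <- fit_ar1(st$segments, "AA", rho = 0, lambda = 5)
  expect_lt(max(abs(f0$coefficients - f2$coefficients)), 1e-8)
})

test_that("the AR(1) working correlation recovers the generating rho", {
  est <- vapply(1:20, function(r) fit_ar1(ar1_segments(100 + r), "1")$rho,
                numeric(1))
  expect_lt(abs(mean(est) - 0.4), 0.1)
  expect_true(all(abs(est) < 1))
})

test_that("non-significant terms are pruned from corrected fits", {
  # strong elevation signal, geographic location pure noise
  seg <- withr::with_seed(77, {
    nt <- 8; np <- 60
    e <- runif(nt * np, 0, 1000)
    tibble::tibble(count = rpois(nt * np, exp(1 + 1.2 * sin(e / 318))),
                   area_km2 = 1, mean_elevation = e,
                   x = runif(nt * np, 0, 5e4), y = runif(nt * np, 0, 5e4),
                   transect_id = rep(sprintf("T%d", 1:nt), each = np),
                   seg_idx = rep(1:np, nt))
  })
  f <- fit_dsm(seg, "AA+GL")
  pruned <- prune_terms(f, seg)
  td <- tidy(pruned)
  # contract: every surviving term is significant at alpha = 0.05
  expect_true(nrow(td) == 0 || all(td$p.value < 0.05))
  expect_false("AA" %in% pruned$dropped_terms)
  expect_true("AA" %in% td$term)
})

test_that("GAM/GAMM comparison reports both CVs without deciding", {
  st <- demo_study()
  f_gam <- fit_dsm(st$segments, "AA")
  f_gamm <- fit_ar1(st$segments, "AA", rho = 0.3)
  grid <- build_grid(st$landscape, cell_area = 1.96)
  cmp <- compare_gam_gamm(f_gam, f_gamm, grid)
  expect_equal(nrow(cmp), 2)
  expect_equal(cmp$rho, c(0, 0.3))
  expect_true(all(cmp$cv >= 0))
  self <- compare_gam_gamm(f_gam, f_gam, grid)
  expect_equal(attr(self, "max_coef_diff"), 0)
  expect_equal(self$abundance[1], self$abundance[2])
})
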