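test_that("grids tile the landscape and apply the forest rule", {
  ls1 <- simulate_landscape(extent_km = c(14, 14), cell_size = 700, seed = 9)
  g <- build_grid(ls1, cell_area = 1.96)
  ct <- attr(g, "counts")
  expect_equal(unname(ct["total"]), 100)   # 14 km / 1.4 km = 10 per side
  expect_equal(unname(ct["excluded"] + ct["retained"]), unname(ct["total"]))
  expect_true(all(g$area_km2 == 1.96))
  expect_identical(g$excluded, g$forest_fraction >= 0.95)

  ls1$forest_fraction[] <- 0
  g0 <- build_grid(ls1, 1.96)
  expect_equal(unname(attr(g0, "counts")["retained"]),
               unname(attr(g0, "counts")["total"]))
  ls1$forest_fraction[] <- 1
  expect_error(build_grid(ls1, 1.96), class = "empty_grid")
  expect_error(build_grid(ls1, cell_area = 500), class = "invalid_argument")
})

test_that("a cell coinciding with a segment strip shares its covariates", {
  ls1 <- simulate_landscape(extent_km = c(14, 14), cell_size = 700, seed = 10)
  g <- build_grid(ls1, 1.96)
  # a segment strip occupying exactly the first grid cell
  side <- sqrt(1.96) * 1000
  seg <- segmentize_transects(
    tibble::tibble(transect_id = "T1", x = c(side / 2, side / 2), y = c(0, side)),
    bandwidth = side)
  seg <- summarize_covariates(seg, ls1)
  cell <- g[g$x == side / 2 & g$y == side / 2, ]
  expect_equal(seg$mean_elevation[1], cell$mean_elevation)
  expect_equal(seg$forest_fraction[1], cell$forest_fraction)
  expect_equal(seg$distance_to_coast[1], cell$distance_to_coast)
})

test_that("intercept-only predictions follow the closed form", {
  seg <- toy_segments(30, seed = 5)
  f <- fit_dsm(seg, "1")
  dens <- exp(f$coefficients[1])
  ls1 <- simulate_landscape(extent_km = c(7, 7), cell_size = 700, seed = 2)
  ls1$forest_fraction[] <- 0
  g <- build_grid(ls1, 1.96)
  s <- predict_cells(f, g)
  expect_equal(s$abundance, rep(dens * 1.96, nrow(s)), tolerance = 1e-10)
  tot <- total_abundance(s)
  expect_equal(tot$density, dens, tolerance = 1e-10)
  # excluded cells never appear
  ls1$forest_fraction[1:2, 1:2] <- 1
  g2 <- build_grid(ls1, 1.96)
  s2 <- predict_cells(f, g2)
  expect_equal(nrow(s2), unname(attr(g2, "counts")["retained"]))
})

test_that("density totals are additive over any partition", {
  st <- demo_study()
  f <- fit_dsm(st$segments, "AA")
  g <- build_grid(st$landscape, 1.96)
  s <- predict_cells(f, g)
  tot <- total_abundance(s)
  expect_equal(tot$abundance, sum(s$abundance))
  expect_equal(tot$density, tot$abundance / tot$area_km2)
  split1 <- s[s$x < median(s$x), ]; split2 <- s[s$x >= median(s$x), ]
  expect_equal(total_abundance(split1)$abundance + total_abundance(split2)$abundance,
               tot$abundance)
})

test_that("grid prediction recovers a constant-intensity population", {
  errs <- vapply(1:8, function(r) {
    ls1 <- simulate_landscape(extent_km = c(28, 21), cell_size = 700,
                              elevation_params = list(sd = 0),
                              forest_params = list(mean = 0.1, steep = 1), seed = r)
    paths <- make_flight_paths(ls1, 5)
    im <- intensity_model(intercept = log(3), group_size = list(dist = "constant", value = 1))
    pop <- simulate_population(ls1, im, seed = r + 50)
    sv <- simulate_survey(pop, paths, 1400, r)
    seg <- summarize_covariates(assign_records(segmentize_transects(paths, 1400, 0),
                                               sv$records), ls1)
    f <- fit_dsm(seg, "1")
    g <- build_grid(ls1, 1.96)
    tot <- total_abundance(predict_cells(f, g))
    true_density <- 3
    (tot$density - true_density) / true_density
  }, numeric(1))
  # mean density estimate within Monte-Carlo error of truth
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)) + 0.03)
})

test_that("zero coefficient covariance gives zero CVs", {
  st <- demo_study()
  f <- fit_dsm(st$segments, "AA")
  f$Vp[] <- 0
  g <- build_grid(st$landscape, 1.96)
  u <- dsm_uncertainty(f, g)
  expect_equal(u$cells$cv, rep(0, nrow(u$cells)))
  expect_equal(u$total$cv, 0)
})

test_that("delta-method and posterior-simulation CVs agree", {
  st <- demo_study()
  f <- fit_dsm(st$segments, "AA")
  g <- build_grid(st$landscape, 1.96)
  ud <- dsm_uncertainty(f, g, method = "delta")
  up <- dsm_uncertainty(f, g, method = "posterior", nsim = 10000, seed = 21)
  expect_lt(abs(ud$total$cv - up$total$cv) / up$total$cv, 0.1)
  expect_true(all(ud$cells$cv > 0))
  expect_true(all(up$cells$cv > 0))
})

test_that("extrapolated cells are flagged and carry larger CVs", {
  seg <- withr::with_seed(8, tibble::tibble(
    count = rpois(120, exp(1 + 0.002 * sort(runif(120, 200, 800)))),
    area_km2 = 1, mean_elevation = sort(runif(120, 200, 800)),
    transect_id = "T", seg_idx = 1:120))
  f <- fit_dsm(seg, "AA")
  newdata <- tibble::tibble(mean_elevation = c(500, 1200), area_km2 = 1)
  pr <- predict(f, newdata, se_fit = TRUE)
  expect_equal(pr$extrapolated, c(FALSE, TRUE))
  expect_gt(pr$se_eta[2], pr$se_eta[1])
  expect_error(predict(f, tibble::tibble(distance_to_coast = 1)),
               class = "schema_error")
})
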