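straight_path <- function(len, id = "T1") {
  tibble::tibble(transect_id = id, x = c(0, 0), y = c(0, len))
}

test_that("segments are bandwidth-length slices with square areas", {
  seg <- segmentize_transects(straight_path(5600), bandwidth = 1400)
  expect_equal(nrow(seg), 4)
  expect_equal(seg$area_km2, rep(1.96, 4))
  expect_equal(seg$length_m, rep(1400, 4))
  expect_equal(seg$seg_idx, 0:3)

  expect_equal(nrow(segmentize_transects(straight_path(2800), 1400)), 2)
})

test_that("terminal remainders follow the min_fraction rule", {
  # 3000 m: 200 m remainder < 0.5 * 1400 -> dropped
  seg <- segmentize_transects(straight_path(3000), 1400, min_fraction = 0.5)
  expect_equal(nrow(seg), 2)
  expect_equal(sum(seg$length_m), 2800)
  # 3500 m: 700 m remainder kept with true length and smaller area
  seg2 <- segmentize_transects(straight_path(3500), 1400, min_fraction = 0.5)
  expect_equal(nrow(seg2), 3)
  expect_equal(seg2$length_m[3], 700)
  expect_equal(seg2$area_km2[3], 0.98)
  expect_equal(sum(seg2$length_m), 3500)
  # min_fraction 0 keeps everything
  seg3 <- segmentize_transects(straight_path(3000), 1400, min_fraction = 0)
  expect_equal(sum(seg3$length_m), 3000)
})

test_that("degenerate paths are rejected", {
  bad <- tibble::tibble(transect_id = "T1", x = c(3, 3), y = c(5, 5))
  expect_error(segmentize_transects(bad, 1400), class = "invalid_argument")
  expect_error(segmentize_transects(straight_path(1000), bandwidth = -1),
               class = "invalid_argument")
})

test_that("record assignment conserves group sizes and respects strips", {
  seg <- segmentize_transects(straight_path(5600), 1400)
  records <- tibble::tibble(
    x = c(seg$x[2], 800, 0, 650),
    y = c(seg$y[2], 2000, 1400, 100),
    group_size = c(5L, 7L, 3L, 2L))
  out <- assign_records(seg, records)
  # at segment 2's centroid -> its count; boundary record at y = 1400 -> segment 1
  expect_equal(out$count[2], 5L)
  expect_equal(out$count[1], 3L + 2L)
  expect_equal(sum(out$count) + sum(unassigned_records(out)$group_size),
               sum(records$group_size))
  # 800 m perpendicular from the centerline is outside the 700 m half-width
  expect_equal(unassigned_records(out)$group_size, 7L)
})

test_that("along-track boundary records go to the lower order index", {
  seg <- segmentize_transects(straight_path(5600), 1400)
  boundary <- tibble::tibble(x = 0, y = 1400, group_size = 1L)
  out <- assign_records(seg, boundary)
  expect_equal(out$count, c(1L, 0L, 0L, 0L))
})

test_that("invalid group sizes are rejected", {
  seg <- segmentize_transects(straight_path(2800), 1400)
  expect_error(assign_records(seg, tibble::tibble(x = 0, y = 1, group_size = 0L)),
               class = "invalid_record")
})

test_that("segment counts reproduce the detected individuals exactly", {
  st <- demo_study()
  expect_equal(sum(st$segments$count) + sum(unassigned_records(st$segments)$group_size),
               sum(st$survey$records$group_size))
  # systematic straight transects fully inside: nothing unassigned
  expect_equal(sum(unassigned_records(st$segments)$group_size), 0)
  # length conservation across the whole design
  expect_equal(sum(st$segments$length_m),
               sum(vapply(split(st$paths, st$paths$transect_id),
                          function(p) stripdsm:::polyline_length(as.matrix(p[, c("x", "y")])),
                          numeric(1))))
})

test_that("covariate summaries are exact on constant rasters", {
  ls1 <- simulate_landscape(extent_km = c(10, 10), cell_size = 1000,
                            elevation_params = list(mean = 100, sd = 0), seed = 1)
  seg <- segmentize_transects(
    tibble::tibble(transect_id = "T1", x = c(5000, 5000), y = c(1000, 8000)), 1400)
  seg <- summarize_covariates(seg, ls1)
  expect_equal(seg$mean_elevation, rep(100, nrow(seg)))
  expect_true(all(seg$forest_fraction >= 0 & seg$forest_fraction <= 1))
  # centroid on the coastline edge
  ls2 <- ls1
  seg2 <- segmentize_transects(
    tibble::tibble(transect_id = "T1", x = c(0, 0), y = c(1000, 4000)), 1400)
  seg2 <- summarize_covariates(seg2, ls2)
  expect_equal(seg2$distance_to_coast, rep(0, nrow(seg2)))
})

test_that("forest exclusion uses the >= 0.95 rule", {
  ls1 <- simulate_landscape(extent_km = c(6, 6), cell_size = 1000, seed = 1)
  ls1$forest_fraction[] <- 0.96
  seg <- segmentize_transects(
    tibble::tibble(transect_id = "T1", x = c(3000, 3000), y = c(500, 4700)), 1400)
  seg <- summarize_covariates(seg, ls1)
  expect_true(all(seg$excluded))
  ls1$forest_fraction[] <- 0.9499
  seg <- summarize_covariates(seg, ls1)
  expect_false(any(seg$excluded))
})

test_that("collinearity screen applies the |r| >= 0.4 rule", {
  n <- 200
  dat <- withr::with_seed(9, {
    x <- rnorm(n)
    # correlated pair in the |r| ~ 0.69 regime seen in field covariates
    tibble::tibble(a = x, b = 0.69 * x + sqrt(1 - 0.69^2) * rnorm(n))
  })
  sc <- collinearity_screen(dat, a, b)
  expect_true(abs(sc$r) > 0.4)
  expect_true(sc$separate_models)

  same <- collinearity_screen(tibble::tibble(a = 1:10, b = 2 * (1:10)), a, b)
  expect_equal(same$r, 1)
  expect_true(same$separate_models)

  orth <- collinearity_screen(tibble::tibble(a = c(-1, 0, 1, 0), b = c(0, 1, 0, 1)), a, b)
  expect_equal(orth$r, 0)
  expect_false(orth$separate_models)

  expect_error(collinearity_screen(tibble::tibble(a = rep(1, 5), b = 1:5), a, b),
               class = "undefined_correlation")
})

test_that("record tallies aggregate by group", {
  rec <- tibble::tibble(season = c("a", "a", "b"), group_size = c(2L, 3L, 4L))
  out <- tally_records(rec, season)
  expect_equal(out$n_records, c(2L, 1L))
  expect_equal(out$individuals, c(5L, 4L))
})
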