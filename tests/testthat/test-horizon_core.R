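test_that("origin defaults to the median of observed values", {
  spec <- horizon_spec()
  expect_equal(compute_origin(c(1, 2, 3, 4, 5), spec), 3)
  expect_equal(compute_origin(c(1, 3), spec), 2)  # even count: midpoint
  fixed <- horizon_spec(origin = 1)
  expect_equal(compute_origin(c(99, 0.1, 7), fixed), 1)
})

test_that("automatic thickness slices the extreme deviation into n_bands", {
  spec <- horizon_spec(n_bands = 4)
  expect_equal(compute_band_thickness(c(0, 8), origin = 0, spec), 2)
  fixed <- horizon_spec(band_thickness = 10)
  expect_equal(compute_band_thickness(c(0, 8), 0, fixed), 10)
  # constant series: sentinel thickness 1
  expect_equal(compute_band_thickness(c(5, 5, 5), 5, spec), 1)
})

test_that("band indices follow the ceil convention with clamping", {
  expect_equal(band_index(0, 1, 4), 0L)
  expect_equal(band_index(2.5, 1, 4), 3L)
  expect_equal(band_index(-10, 1, 4), -4L)
  # boundary: exactly k * thickness belongs to band k
  expect_equal(band_index(2, 1, 4), 2L)
  expect_equal(band_index(3 * 0.1, 0.1, 4), 3L)  # floating-point boundary
  expect_error(band_index(1, 0, 4), "positive")
})

test_that("band fills implement the clamp formula", {
  z <- band_fills(0, 1, 4)
  expect_equal(z$fills, c(0, 0, 0, 0))
  expect_equal(z$sign, 0)
  f <- band_fills(2.5, 1, 4)
  expect_equal(f$fills, c(1, 1, 0.5, 0))
  expect_equal(f$sign, 1)
  g <- band_fills(-7, 1, 4)
  expect_equal(g$fills, c(1, 1, 1, 1))  # saturates beyond 4 * thickness
  expect_equal(g$sign, -1)
})

test_that("fills agree with the interval-intersection oracle and conserve mass", {
  set.seed(202)
  for (i in 1:2000) {
    d <- stats::runif(1, -30, 30)
    t <- stats::runif(1, 0.05, 10)
    n <- sample(1:8, 1L)
    got <- band_fills(d, t, n)
    expect_equal(got$fills, oracle_fills(d, t, n), tolerance = 1e-12)
    expect_equal(sum(got$fills), min(abs(d), n * t), tolerance = 1e-12)
    expect_true(all(diff(got$fills) <= 1e-12))      # monotone in k
    expect_true(all(got$fills >= 0 & got$fills <= t + 1e-12))
    expect_equal(band_index(d, t, n), oracle_band_index(d, t, n))
  }
})

test_that("the transform is mirror-symmetric and odd in the deviation", {
  set.seed(303)
  for (i in 1:500) {
    d <- stats::runif(1, 0, 20)
    t <- stats::runif(1, 0.1, 5)
    n <- sample(1:6, 1L)
    expect_equal(band_fills(d, t, n)$fills, band_fills(-d, t, n)$fills)
    expect_equal(band_index(-d, t, n), -band_index(d, t, n))
  }
})

test_that("shrinking the thickness never moves a point to a less extreme band", {
  set.seed(404)
  for (i in 1:300) {
    d <- stats::runif(1, -20, 20)
    t1 <- stats::runif(1, 0.1, 5)
    t2 <- t1 * stats::runif(1, 0.1, 1)  # t2 <= t1
    expect_gte(abs(band_index(d, t2, 4)), abs(band_index(d, t1, 4)))
  }
})

test_that("the full transform saturates its extreme point under auto scaling", {
  set.seed(505)
  for (i in 1:50) {
    n_pts <- sample(4:12, 1L)
    s <- make_series(random_times(n_pts), stats::runif(n_pts, 0, 40))
    hb <- build_horizon(s, horizon_spec(n_bands = 4))
    expect_true(all(abs(hb$band_index) <= 4))
    worst <- which.max(abs(hb$deviations))
    expect_equal(abs(hb$band_index[worst]), 4L)
    expect_equal(hb$fills[worst, ], rep(hb$thickness, 4),
                 tolerance = 1e-12)
    # conservation at every point
    expect_equal(rowSums(hb$fills),
                 pmin(abs(hb$deviations), 4 * hb$thickness),
                 tolerance = 1e-12)
  }
})

test_that("negating deviations mirrors the horizon output", {
  set.seed(606)
  s <- make_series(random_times(8), stats::runif(8, 0, 10))
  spec <- horizon_spec(origin = 5, band_thickness = 1.5)
  hb <- build_horizon(s, spec)
  flipped_vals <- 2 * 5 - s$values  # reflect values about the origin
  s2 <- make_series(s$times, pmax(flipped_vals, 0))
  keep <- flipped_vals >= 0        # only compare points that stay valid
  hb2 <- build_horizon(s2, spec)
  expect_equal(hb2$band_index[keep], -hb$band_index[keep])
  expect_equal(hb2$fills[keep, ], hb$fills[keep, ])
})

test_that("constant series are degenerate, warned about, and all-zero", {
  s <- make_series(c(0, 10, 20), c(7, 7, 7))
  expect_warning(hb <- build_horizon(s, horizon_spec()), "constant")
  expect_true(hb$degenerate)
  expect_equal(hb$thickness, 1)
  expect_true(all(hb$fills == 0))
  expect_true(all(hb$band_index == 0L))
})

test_that("a single band degenerates to a clipped area plot", {
  s <- make_series(c(0, 10, 20, 30), c(0, 2, 9, 4))
  hb <- build_horizon(s, horizon_spec(origin = 0, band_thickness = 3,
                                      n_bands = 1))
  expect_equal(as.numeric(hb$fills), pmin(abs(hb$deviations), 3))
})

test_that("global scaling pools deviations into one shared thickness", {
  s1 <- make_series(c(0, 10, 20), c(0, 4, 8))    # extreme deviation 4
  s2 <- make_series(c(0, 10, 20), c(0, 20, 40))  # extreme deviation 20
  spec <- horizon_spec(n_bands = 4, fixed_scale = TRUE)
  ctx <- list(s1, s2)
  h1 <- build_horizon(s1, spec, panel_context = ctx)
  h2 <- build_horizon(s2, spec, panel_context = ctx)
  expect_equal(h1$thickness, 5)  # 20 / 4, shared
  expect_equal(h2$thickness, 5)
  # per-series scaling instead gives each its own
  expect_equal(build_horizon(s1, horizon_spec())$thickness, 1)
})

test_that("interpolation cannot shift the origin or the scale", {
  s <- make_series(c(0, 30, 65), c(2, 8, 5))
  g <- grid_spec(25, 1000)
  interp <- interpolate_regular(s, g)
  hb <- build_horizon(interp, horizon_spec(), calibration = s)
  expect_equal(hb$origin, stats::median(c(2, 8, 5)))
  expect_equal(hb$thickness, max(abs(c(2, 8, 5) - 5)) / 4)
})
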