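test_that("dates convert to day offsets from the first sample", {
  expect_equal(dates_to_days(as.Date(c("2020-01-01", "2020-01-26"))),
               c(0L, 25L))
  # 2020 is a leap year: Feb 28 -> Mar 1 is two days
  expect_equal(dates_to_days(as.Date(c("2020-02-28", "2020-03-01"))),
               c(0L, 2L))
  expect_equal(dates_to_days(as.Date("2020-06-01")), 0L)
})

test_that("segments break after gaps strictly greater than max_gap", {
  expect_equal(split_segments(c(0, 50, 150), 75), c(1L, 1L, 2L))
  expect_equal(split_segments(c(0, 75), 75), c(1L, 1L))      # == is no break
  expect_equal(split_segments(c(0, 76), 75), c(1L, 2L))
  expect_equal(split_segments(c(0, 200, 400), 75), c(1L, 2L, 3L))
  expect_error(split_segments(c(0, 0, 5), 75), "strictly increasing")
})

test_that("grid specs validate their parameters", {
  expect_error(grid_spec(regular_interval = -5), "positive")
  expect_error(grid_spec(regular_interval = 25, max_gap = 10), ">=")
  g <- grid_spec(regular_interval = 25)
  expect_true(g$enabled)
  expect_equal(g$max_gap, Inf)
  expect_false(grid_spec()$enabled)
})

test_that("regularization interpolates linearly onto the segment grid", {
  s <- make_series(c(0, 50), c(0, 10))
  out <- interpolate_regular(s, grid_spec(25, 1000))
  expect_equal(out$times, c(0, 25, 50))
  expect_equal(out$values, c(0, 5, 10))
  expect_equal(out$observed, c(TRUE, FALSE, TRUE))

  # already regular: identity
  s2 <- make_series(c(0, 10, 20, 30), c(1, 2, 3, 4))
  out2 <- interpolate_regular(s2, grid_spec(10, 1000))
  expect_equal(out2$times, s2$times)
  expect_equal(out2$values, s2$values)
  expect_true(all(out2$observed))

  # a gap beyond max_gap yields singleton segments with no interpolation
  s3 <- make_series(c(0, 100), c(1, 9), max_gap = 75)
  out3 <- interpolate_regular(s3, grid_spec(25, 75))
  expect_equal(out3$times, c(0, 100))
  expect_equal(out3$segment_id, c(1L, 2L))
  expect_true(all(out3$observed))
})

test_that("segment endpoints are retained and off-grid interiors dropped", {
  s <- make_series(c(0, 30, 65), c(2, 8, 5))
  out <- interpolate_regular(s, grid_spec(25, 1000))
  expect_equal(out$times, c(0, 25, 50, 65))       # 30 dropped, 65 kept
  expect_equal(out$values[c(1, 4)], c(2, 5))      # endpoint pass-through
  expect_equal(out$observed, c(TRUE, FALSE, FALSE, TRUE))
  # interior grid values follow the piecewise-linear observed path
  expect_equal(out$values[2], oracle_line(0, 2, 30, 8, 25))
  expect_equal(out$values[3], oracle_line(30, 8, 65, 5, 50))
})

test_that("no points are created across segment gaps or beyond series ends", {
  s <- make_series(c(0, 20, 150, 170), c(1, 2, 3, 4), max_gap = 75)
  out <- interpolate_regular(s, grid_spec(10, 75))
  expect_false(any(out$times > 20 & out$times < 150))
  expect_equal(range(out$times), c(0, 170))
  # spacing within a segment equals the interval except final sub-interval
  for (seg in unique(out$segment_id)) {
    d <- diff(out$times[out$segment_id == seg])
    if (length(d) > 1L) expect_true(all(d[-length(d)] == 10))
    expect_true(all(d <= 10))
  }
})

test_that("interpolation matches the two-point line oracle on random series", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:9, 1L)
    times <- random_times(n)
    if (anyDuplicated(times)) next
    vals <- round(stats::runif(n, 0, 50), 3)
    interval <- sample(2:15, 1L)
    s <- make_series(times, vals, max_gap = 1e6)
    out <- interpolate_regular(s, grid_spec(interval, 1e6))
    # observed points pass through exactly
    expect_true(all(times %in% out$times[out$observed] |
                      !(times %in% out$times)))
    for (j in which(!out$observed)) {
      t <- out$times[j]
      lo <- max(which(times <= t)); hi <- min(which(times >= t))
      expected <- oracle_line(times[lo], vals[lo], times[hi], vals[hi], t)
      expect_equal(out$values[j], expected, tolerance = 1e-10)
      # bounded by bracketing observations
      expect_gte(out$values[j], min(vals[lo], vals[hi]) - 1e-10)
      expect_lte(out$values[j], max(vals[lo], vals[hi]) + 1e-10)
    }
  }
})

test_that("regularization is idempotent and disabled grids pass through", {
  set.seed(77)
  times <- random_times(8)
  vals <- stats::runif(8, 0, 20)
  s <- make_series(times, vals, max_gap = 40)
  g <- grid_spec(7, 40)
  once <- interpolate_regular(s, g)
  twice <- interpolate_regular(once, g)
  expect_equal(twice$times, once$times)
  expect_equal(twice$values, once$values)
  expect_equal(twice$observed, once$observed)

  off <- interpolate_regular(s, grid_spec())
  expect_identical(off, s)
})

test_that("series construction from a table preserves values and segments", {
  we <- generate_worked_example()
  meta <- we$metadata
  s <- build_series(we$table, meta, "OTU_001", grid_spec(7, 75))
  expect_equal(s$times, seq(0, 28, by = 7))
  expect_equal(s$values, c(10, 20, 30, 40, 50))
  expect_equal(s$segment_id, rep(1L, 5))
  expect_error(build_series(we$table, meta, "nope"), "unknown taxon")
})
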