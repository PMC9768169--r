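mk_pair <- function(mcp, pcp, dt = 1) {
  list(times = (seq_along(mcp) - 1) * dt, mcp = mcp, pcp = pcp)
}

test_that("a trace against itself peaks at 1.0 at lag zero", {
  set.seed(31)
  x <- cumsum(rnorm(120))
  cc <- ccf_average(list(mk_pair(x, x)), max_lag = 10)
  expect_equal(cc$peak_lag_min, 0)
  expect_equal(max(cc$table$mean_r), 1, tolerance = 1e-12)
})

test_that("a shifted copy peaks at the shift", {
  set.seed(32)
  x <- abs(cumsum(rnorm(200)))
  y <- c(rep(0, 3), x[1:197])  # y lags x by 3 samples
  cc <- ccf_average(list(mk_pair(x, y)), max_lag = 15)
  expect_equal(cc$peak_lag_min, 3)
})

test_that("swapping the traces negates the peak lag", {
  set.seed(33)
  x <- abs(cumsum(rnorm(150)))
  y <- c(rep(0, 4), x[1:146])
  a <- ccf_average(list(mk_pair(x, y)), max_lag = 12)
  b <- ccf_average(list(mk_pair(y, x)), max_lag = 12)
  expect_equal(a$peak_lag_min, -b$peak_lag_min)
})

test_that("white-noise pairs show no spurious correlation structure", {
  cover <- c(); maxr <- c()
  for (s in 1:50) {
    set.seed(600 + s)
    pairs <- lapply(1:20, function(i)
      mk_pair(rnorm(120), rnorm(120)))
    cc <- ccf_average(pairs, max_lag = 10)
    maxr <- c(maxr, max(abs(cc$table$mean_r)))
    cover <- c(cover, mean(cc$table$ci_lo <= 0 & cc$table$ci_hi >= 0))
  }
  expect_true(all(maxr < 0.2))
  expect_gte(mean(cover), 0.90)
})

test_that("zero-variance cells are excluded with a warning", {
  set.seed(34)
  good <- mk_pair(rnorm(50), rnorm(50))
  flat <- mk_pair(rep(1, 50), rnorm(50))
  expect_warning(cc <- ccf_average(list(good, flat), max_lag = 5),
                 "zero-variance")
  expect_equal(cc$n_cells, 1L)
  expect_error(suppressWarnings(ccf_average(list(flat), max_lag = 5)),
               "no usable")
})

test_that("delay and rate follow the printed separation arithmetic", {
  set.seed(35)
  x <- abs(rnorm(240))
  y <- c(rep(0, 4), x[1:236])
  cc <- ccf_average(list(mk_pair(x, y)), max_lag = 20)
  dr <- delay_and_rate(cc, separation_kb = 11.2)
  expect_equal(dr$delay_min, 4)
  expect_equal(dr$rate_kb_per_min, 2.8)

  # identity: delay = separation / r recovers r for any r
  for (r in c(0.5, 2, 3.7)) {
    sep <- 4 * r
    expect_equal(delay_and_rate(cc, sep)$rate_kb_per_min, r)
  }
})

test_that("parabolic interpolation is exact for symmetric flanks", {
  cc <- structure(list(
    table = data.frame(lag_min = -3:3,
                       mean_r = c(0.05, 0.1, 0.2, 0.5, 0.9, 0.5, 0.2)),
    peak_lag_min = 1, n_cells = 1L, max_lag = 3L, dt_min = 1),
    class = "ccf_result")
  # symmetric flanking values: the parabola vertex is the discrete peak
  dr <- delay_and_rate(cc, 11.2, interpolate = TRUE)
  expect_equal(dr$delay_min, 1)
  expect_error(delay_and_rate(cc, -1), "separation_kb")
})

test_that("edge peaks and non-positive delays raise errors", {
  tb <- data.frame(lag_min = -3:3, mean_r = c(1, .2, .1, .1, .1, .1, .05))
  cc <- structure(list(table = tb, peak_lag_min = -3, n_cells = 1L,
                       max_lag = 3L, dt_min = 1), class = "ccf_result")
  expect_error(delay_and_rate(cc, 5), "edge")
  tb2 <- data.frame(lag_min = -3:3, mean_r = c(.1, .2, 1, .2, .1, .05, 0))
  cc2 <- structure(list(table = tb2, peak_lag_min = -1, n_cells = 1L,
                        max_lag = 3L, dt_min = 1), class = "ccf_result")
  expect_error(delay_and_rate(cc2, 5), "rate undefined")
})
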