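test_that("nearest distance applies the pixel calibration", {
  anchor <- list(y_px = 10, x_px = 10)
  one <- data.frame(y_px = 11, x_px = 10)
  expect_equal(nearest_distance(anchor, one)$distance_nm, 130)
  coincident <- data.frame(y_px = 10, x_px = 10)
  expect_equal(nearest_distance(anchor, coincident)$distance_nm, 0)
  none <- nearest_distance(anchor, one[0, ])
  expect_true(is.na(none$distance_nm))
  expect_match(none$reason, "no clusters")
})

test_that("nearest distance equals an exhaustive scan and is translation invariant", {
  set.seed(41)
  anchor <- list(y_px = 20.3, x_px = 19.1)
  cl <- data.frame(y_px = runif(50, 0, 40), x_px = runif(50, 0, 40))
  rec <- nearest_distance(anchor, cl)
  d_oracle <- Inf
  for (i in 1:50) {
    d <- sqrt((cl$y_px[i] - anchor$y_px)^2 +
                (cl$x_px[i] - anchor$x_px)^2) * 130
    if (d < d_oracle) d_oracle <- d
  }
  expect_equal(rec$distance_nm, d_oracle)
  shifted <- nearest_distance(list(y_px = anchor$y_px + 7,
                                   x_px = anchor$x_px - 3),
                              data.frame(y_px = cl$y_px + 7,
                                         x_px = cl$x_px - 3))
  expect_equal(shifted$distance_nm, rec$distance_nm)
})

test_that("exact rank-sum p-value matches wilcox.test enumeration", {
  # no ties: the closed-form exact test is the oracle
  p_pkg <- rank_sum_exact(c(1, 2, 3), c(4, 5, 6))
  p_ref <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p.value
  expect_equal(p_pkg, p_ref)
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(rank_sum_exact(a, b),
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # identical groups under exact tie handling
  expect_equal(rank_sum_exact(c(1, 2, 3), c(1, 2, 3)), 1)
})

test_that("stratified comparison splits at the distance threshold", {
  rec <- data.frame(distance_nm = c(100, 200, 350, 400, 500, 600),
                    state = c("ON", "ON", "ON", "OFF", "OFF", "OFF"))
  res <- stratified_comparison(rec)
  expect_equal(res$summary$n, c(3L, 3L))  # 350 goes to the short group
  expect_equal(res$p_value, rank_sum_exact(c(100, 200, 350),
                                           c(400, 500, 600)))
  # all on one side: explicit no-test, not an exception
  res1 <- stratified_comparison(data.frame(distance_nm = c(10, 20, 30),
                                           state = "ON"))
  expect_true(is.na(res1$p_value))
  expect_match(res1$reason, "empty")
  # large samples switch to the tie-corrected normal approximation
  set.seed(43)
  rec2 <- data.frame(distance_nm = c(runif(15, 0, 340), runif(15, 360, 900)),
                     state = "ON")
  res2 <- stratified_comparison(rec2)
  expect_match(res2$method, "normal approximation")
  expect_lt(res2$p_value, 0.01)
})

test_that("FWHM of a noiseless Gaussian is 2.355 sigma", {
  roi <- render_gaussians(19, 19, cbind(9, 9), amplitude = 50, sigma = 2,
                          background = 10)
  res <- cluster_fwhm(list(roi))
  expect_lt(abs(res$fwhm_px - 2 * sqrt(2 * log(2)) * 2) /
              (2 * sqrt(2 * log(2)) * 2), 0.01)
  expect_lt(abs(res$fwhm_nm - 612), 7)
  expect_lt(max(abs(res$center_px - c(9, 9))), 0.05)
})

test_that("ROI averaging suppresses background noise as 1/sqrt(N)", {
  noisy_roi <- function(s) {
    set.seed(s)
    render_gaussians(19, 19, cbind(9, 9), amplitude = 60, sigma = 1.5,
                     background = 20) + matrix(rnorm(361, 0, 5), 19, 19)
  }
  resid_sd <- function(n) {
    res <- cluster_fwhm(lapply(1:n, noisy_roi))
    model <- res$mean_image
    fit <- fit_gaussian_2d(model, sigma0 = 1.5)
    yy <- rep(0:18, 19); xx <- rep(0:18, each = 19)
    pred <- fit$offset + fit$amplitude *
      exp(-((yy - fit$y0)^2 + (xx - fit$x0)^2) / (2 * fit$sigma^2))
    sd(as.numeric(model) - pred)
  }
  r4 <- resid_sd(4); r36 <- resid_sd(36)
  expect_lt(abs(r4 / r36 - 3), 1.2)
  expect_error(cluster_fwhm(list(matrix(0, 5, 5), matrix(0, 7, 7))),
               "same shape")
})

test_that("detection plus nearest-distance recovers generating medians per state", {
  run_state <- function(state, median_nm, n) {
    vapply(1:n, function(i)
      analyze_cluster_scene_once(state, median_nm, 3, 1.3, 0.5,
                                 seed = 5000 + i)$record$distance_nm,
      0)
  }
  d_on <- suppressWarnings(run_state("ON", 289, 250))
  d_off <- suppressWarnings(run_state("OFF", 456, 250))
  expect_lt(abs(median(d_on, na.rm = TRUE) - 289) / 289, 0.08)
  expect_lt(abs(median(d_off, na.rm = TRUE) - 456) / 456, 0.08)
})
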