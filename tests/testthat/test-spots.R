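test_that("noiseless Gaussian spot is localized within 0.05 px", {
  img <- render_gaussians(71, 41, cbind(50.3, 20.7), amplitude = 100,
                          sigma = 1.5, background = 10)
  sp <- detect_and_refine(img, threshold = 20)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$y_px - 50.3), 0.05)
  expect_lt(abs(sp$x_px - 20.7), 0.05)
  expect_true(sp$fit_ok)
})

test_that("well-separated spots match a brute-force maxima scan", {
  centers <- cbind(c(15, 15), c(10, 20))
  img <- render_gaussians(31, 31, centers, amplitude = c(100, 90),
                          sigma = 1.3, background = 5)
  sp <- detect_and_refine(img, threshold = 20)
  expect_equal(nrow(sp), 2L)
  # oracle: exhaustive neighbourhood scan for integer-grid maxima
  oracle <- c()
  for (r in 2:30) for (cc in 2:30) {
    nb <- img[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    if (img[r, cc] == max(nb) && img[r, cc] > 20)
      oracle <- rbind(oracle, c(r - 1, cc - 1))
  }
  oracle <- oracle[order(oracle[, 2]), , drop = FALSE]
  sp <- sp[order(sp$x_px), ]
  expect_equal(nrow(oracle), 2L)
  expect_lt(max(abs(sp$y_px - oracle[, 1])), 0.1)
  expect_lt(max(abs(sp$x_px - oracle[, 2])), 0.1)
})

test_that("noise-only images yield no detections at a 5-sigma threshold", {
  n_clean <- 0L
  for (s in 1:100) {
    set.seed(s)
    img <- matrix(rnorm(48 * 48, 100, 3), 48, 48)
    sp <- suppressWarnings(
      detect_and_refine(img, threshold = 100 + 5 * 3))
    if (nrow(sp) == 0L) n_clean <- n_clean + 1L
  }
  expect_gte(n_clean, 99L)
})

test_that("anchored ROI detection reports the window mean", {
  img <- render_gaussians(41, 41, cbind(20.2, 20.6), amplitude = 60,
                          sigma = 1.4, background = 10)
  sp <- detect_and_refine(img, roi = c(20, 20), max_candidates = 1)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$y_px - 20.2), 0.05)
  r <- 12:30  # rows/cols of the 19x19 window around (20, 20), 1-based
  expect_equal(attr(sp, "roi_mean"), mean(img[r, r]))
})

test_that("border candidates are dropped with a warning", {
  img <- render_gaussians(31, 31, cbind(2, 15), amplitude = 100,
                          sigma = 1.3, background = 5)
  expect_warning(sp <- detect_and_refine(img, threshold = 20),
                 "border")
  expect_equal(nrow(sp), 0L)
})

test_that("disk mean matches a naive per-pixel oracle", {
  img <- render_gaussians(31, 31, cbind(14.6, 16.2), amplitude = 70,
                          sigma = 2, background = 20)
  m <- measure_spot(img, c(14.6, 16.2), radius_px = 6)
  expect_equal(m$disk_mean, disk_mean_oracle(img, c(14.6, 16.2), 6))
  expect_false(m$partial)

  # uniform image: disk mean = value, relative intensity 1
  u <- measure_spot(matrix(7, 21, 21), c(10, 10), radius_px = 6,
                    nucleus_mean = 7)
  expect_equal(u$disk_mean, 7)
  expect_equal(u$relative_intensity, 1)

  # global scaling: disk mean scales, relative intensity unchanged
  m2 <- measure_spot(img * 3, c(14.6, 16.2), radius_px = 6,
                     nucleus_mean = 3 * 20)
  expect_equal(m2$disk_mean, 3 * m$disk_mean)
  expect_equal(m2$relative_intensity,
               measure_spot(img, c(14.6, 16.2), radius_px = 6,
                            nucleus_mean = 20)$relative_intensity)
  expect_error(measure_spot(img, c(14, 14), nucleus_mean = 0), "<= 0")
})

test_that("SNR is the spot mean over the nuclear SD", {
  img <- matrix(0, 31, 31)
  img[disk_mask(31, 31, c(15, 15), 4)] <- 10
  expect_equal(compute_snr(img, c(15, 15), nucleus_sd = 2), 5)
  expect_equal(compute_snr(img * 4, c(15, 15), nucleus_sd = 8), 5)
  expect_error(compute_snr(img, c(15, 15), nucleus_sd = 0), "SD is 0")
})

test_that("SNR on noisy synthetic nuclei is close to construction", {
  snrs <- vapply(1:50, function(s) {
    set.seed(s)
    img <- matrix(rnorm(41 * 41, 0, 3), 41, 41)
    img[disk_mask(41, 41, c(20, 20), 3)] <-
      img[disk_mask(41, 41, c(20, 20), 3)] + 30
    sigma_n <- sd(img[!disk_mask(41, 41, c(20, 20), 6)])
    compute_snr(img, c(20, 20), nucleus_sd = sigma_n)
  }, 0)
  expect_lt(abs(mean(snrs) - 10) / 10, 0.1)
})

test_that("focus counting honours the prominence threshold", {
  flat <- matrix(5, 31, 31)
  mask <- matrix(TRUE, 31, 31)
  expect_equal(count_foci(flat, mask, 10)$count, 0L)

  centers <- cbind(c(6, 6, 16, 25, 25), c(6, 24, 15, 6, 24))
  img <- render_gaussians(31, 31, centers, amplitude = 20, sigma = 1.2,
                          background = 5)
  res <- count_foci(img, mask, 10)
  expect_equal(res$count, 5L)
  expect_equal(res$mean_intensity, mean(res$peaks$value))
  expect_equal(count_foci(img, mask, 30)$count, 0L)
  expect_error(count_foci(img, matrix(FALSE, 31, 31), 10), "empty")
})

test_that("linking keeps a stationary spot as one retained track", {
  spots <- data.frame(frame = 1:60, y_px = 10 + rnorm(60, 0, 0.1),
                      x_px = 12 + rnorm(60, 0, 0.1))
  tr <- link_tracks(spots, min_consecutive = 50)
  expect_equal(length(unique(tr$track)), 1L)
  expect_equal(nrow(tr), 60L)
})

test_that("gap tolerance follows the linking memory", {
  frames <- c(1:10, 14:20)  # 3-frame gap
  spots <- data.frame(frame = frames, y_px = 5, x_px = 5)
  t_mem4 <- link_tracks(spots, memory_frames = 4, min_consecutive = 2)
  expect_equal(length(unique(t_mem4$track)), 1L)
  t_mem2 <- link_tracks(spots, memory_frames = 2, min_consecutive = 2)
  expect_equal(length(unique(t_mem2$track)), 2L)
})

test_that("the consecutive-frames filter is strict", {
  mk <- function(n) data.frame(frame = seq_len(n), y_px = 1, x_px = 1)
  expect_equal(nrow(link_tracks(mk(49), min_consecutive = 50)), 0L)
  expect_equal(nrow(link_tracks(mk(51), min_consecutive = 50)), 51L)
})

test_that("linking is invariant to spot order within frames", {
  set.seed(8)
  spots <- do.call(rbind, lapply(1:30, function(f)
    data.frame(frame = f,
               y_px = c(5, 15) + rnorm(2, 0, 0.2),
               x_px = c(5, 15) + rnorm(2, 0, 0.2))))
  shuffled <- spots[sample(nrow(spots)), ]
  a <- link_tracks(spots, min_consecutive = 10)
  b <- link_tracks(shuffled, min_consecutive = 10)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
})
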