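test_that("rolling ball removes a flat background completely", {
  st <- image_stack(matrix(37, 24, 24))
  out <- preprocess(st, list(list(op = "rolling_ball", radius = 5)))
  expect_true(all(out$pixels == 0))
  expect_equal(out$provenance[[1L]]$op, "rolling_ball")
})

test_that("rolling ball never yields negative intensities", {
  set.seed(2)
  m <- matrix(runif(32 * 32, 10, 40), 32, 32)
  m[10:13, 20:23] <- 200
  out <- preprocess(image_stack(m),
                    list(list(op = "rolling_ball", radius = 4)))
  expect_true(all(out$pixels >= 0))
})

test_that("max projection keeps the brightest voxel in place", {
  arr <- array(1, dim = c(3, 8, 8))   # (z, y, x)
  arr[2, 5, 3] <- 99
  st <- image_stack(arr, axes = "zyx")
  out <- preprocess(st, list(list(op = "max_project")))
  expect_equal(dim(out$pixels), c(8L, 8L))
  expect_equal(out$pixels[5, 3], 99)
  expect_true(all(out$pixels[-(5 + 2 * 8)] == 1))
})

test_that("gaussian blur conserves intensity away from borders", {
  img <- render_gaussians(41, 41, cbind(20, 20), amplitude = 100,
                          sigma = 2)
  out <- preprocess(image_stack(img),
                    list(list(op = "gaussian", sigma = 1)))
  expect_lt(abs(sum(out$pixels) / sum(img) - 1), 0.005)
})

test_that("median filter suppresses salt noise on a constant image", {
  m <- matrix(10, 21, 21); m[11, 11] <- 1000
  out <- preprocess(image_stack(m), list(list(op = "median", radius = 1)))
  expect_equal(out$pixels[11, 11], 10, tolerance = 0.01)
})

test_that("drift correction recovers an injected integer shift", {
  set.seed(3)
  base <- render_gaussians(32, 32, cbind(c(10, 22, 15), c(8, 20, 27)),
                           amplitude = c(100, 80, 60), sigma = 1.5,
                           background = 5)
  arr <- array(0, dim = c(3, 32, 32))
  arr[1, , ] <- base
  arr[2, , ] <- txspot:::shift_image(base, 3, -2, fill = 5)
  arr[3, , ] <- txspot:::shift_image(base, -4, 5, fill = 5)
  st <- image_stack(arr, axes = "tyx")
  out <- preprocess(st, list(list(op = "drift_correct")))
  shifts <- attr(out, "drift_shifts")
  expect_equal(shifts[2, ], c(3, -2))
  expect_equal(shifts[3, ], c(-4, 5))
  # interior pixels restored exactly
  expect_equal(out$pixels[2, 10:20, 10:20], arr[1, 10:20, 10:20])
})

test_that("simple-ratio bleach correction equalizes frame means", {
  set.seed(4)
  arr <- array(0, dim = c(4, 16, 16))
  decay <- c(1, 0.8, 0.65, 0.5)
  for (t in 1:4) arr[t, , ] <- matrix(runif(256, 50, 60), 16, 16) * decay[t]
  st <- image_stack(arr, axes = "tyx")
  out <- preprocess(st, list(list(op = "bleach_correct")))
  means <- apply(out$pixels, 1, mean)
  expect_equal(means, rep(means[1L], 4), tolerance = 1e-10)
})

test_that("invalid steps are rejected with informative errors", {
  st <- image_stack(matrix(1, 8, 8))
  expect_error(preprocess(st, list(list(op = "sharpen"))), "unknown")
  expect_error(preprocess(st, list(list(op = "gaussian", sigma = -1))),
               "sigma > 0")
  expect_error(preprocess(st, list(list(op = "max_project"))), "z axis")
})

test_that("nucleus measurement matches per-pixel statistics", {
  m <- matrix(0, 40, 40)
  mask <- matrix(0L, 40, 40)
  d1 <- disk_mask(40, 40, c(10, 10), 6); d2 <- disk_mask(40, 40, c(28, 30), 5)
  m[d1] <- 10; mask[d1] <- 1L
  set.seed(5); m[d2] <- rnorm(sum(d2), 50, 4); mask[d2] <- 2L
  rec <- measure_nuclei(image_stack(m), mask)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$mean[1L], 10)
  expect_equal(rec$sd[1L], 0)
  expect_equal(rec$com_y_nm[1L] / 130, 10, tolerance = 1e-9)
  # brute-force per-label loop
  expect_equal(rec$mean[2L], mean(m[mask == 2L]))
  expect_equal(rec$sd[2L], sd(m[mask == 2L]))
  idx <- which(mask == 2L, arr.ind = TRUE) - 1L
  w <- m[mask == 2L] / sum(m[mask == 2L])
  expect_equal(rec$com_x_nm[2L], sum(w * idx[, 2L]) * 130)
  expect_error(measure_nuclei(image_stack(m), matrix(0L, 40, 40)), "empty")
  expect_error(measure_nuclei(image_stack(m), matrix(1L, 4, 4)), "mismatch")
})

test_that("auto segmentation finds bright disks", {
  m <- matrix(5, 64, 64)
  m[disk_mask(64, 64, c(20, 20), 9)] <- 100
  m[disk_mask(64, 64, c(45, 45), 8)] <- 90
  rec <- measure_nuclei(image_stack(m), "auto")
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$mean > 80))
})

test_that("TIFF round trip preserves pixels and calibration", {
  arr <- array(round(runif(2 * 12 * 12) * 1000), dim = c(2, 12, 12))
  st <- image_stack(arr, axes = "tyx", pixel_size_nm = 130,
                    frame_interval_s = 0.03)
  path <- tempfile(fileext = ".tif")
  write_image_stack(st, path)
  back <- read_image_stack(path)
  expect_equal(back$pixels, st$pixels)
  expect_equal(back$pixel_size_nm, 130)
  expect_equal(back$axes, "tyx")
})
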