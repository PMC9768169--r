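test_that("empty scene renders to the constant background", {
  sc <- ground_truth_scene(16, 16, data.frame(), background = 42)
  st <- render_scene(sc)
  expect_true(all(st$pixels == 42))
})

test_that("rendered spot conserves the analytic Gaussian integral", {
  A <- 80; s <- 1.7
  sc <- ground_truth_scene(41, 41,
                           data.frame(channel = 1L, frame = 1L,
                                      y_px = 20.4, x_px = 19.6,
                                      amplitude = A, sigma_px = s),
                           background = 10)
  img <- stack_plane(render_scene(sc))
  integral <- sum(img) - 41 * 41 * 10
  expect_lt(abs(integral / (2 * pi * A * s^2) - 1), 0.01)
})

test_that("disk mean is linear in spot amplitude", {
  mk <- function(A) {
    sc <- ground_truth_scene(31, 31,
                             data.frame(channel = 1L, frame = 1L,
                                        y_px = 15, x_px = 15,
                                        amplitude = A, sigma_px = 1.3),
                             background = 50)
    stack_plane(render_scene(sc))
  }
  m1 <- measure_spot(mk(100), c(15, 15), radius_px = 6)$disk_mean - 50
  m2 <- measure_spot(mk(200), c(15, 15), radius_px = 6)$disk_mean - 50
  expect_equal(m2, 2 * m1, tolerance = 1e-10)
})

test_that("scene construction rejects out-of-frame spots", {
  expect_error(ground_truth_scene(16, 16,
                                  data.frame(channel = 1L, frame = 1L,
                                             y_px = 20, x_px = 5,
                                             amplitude = 1, sigma_px = 1)),
               "inside the frame")
  expect_error(ground_truth_scene(16, 16,
                                  data.frame(channel = 1L, frame = 1L,
                                             y_px = 5, x_px = 5,
                                             amplitude = 1, sigma_px = 0)),
               "sigma_px")
})

test_that("cluster scenes honour the configured nearest-distance law", {
  # degenerate case: zero median, zero dispersion -> colocalized
  sc0 <- simulate_cluster_scene("ON", 0, n_clusters = 1, dispersion = 0,
                                seed = 1)
  expect_equal(sc0$truth$nearest_distance_nm, 0, tolerance = 1e-9)

  # ground-truth nearest equals a brute-force scan over all clusters,
  # and decoys never undercut the designated nearest cluster
  for (s in 1:20) {
    sc <- simulate_cluster_scene("ON", 289, n_clusters = 4, seed = s)
    d_all <- sqrt(colSums((t(sc$truth$clusters_px) -
                             sc$truth$anchor_px)^2)) * 130
    expect_equal(sc$truth$nearest_distance_nm, min(d_all))
    expect_equal(unname(which.min(d_all)), 1L)
  }

  # the empirical median over many scenes matches the configured median
  d <- vapply(1:1000, function(s)
    simulate_cluster_scene("ON", 289, n_clusters = 1,
                           shot_noise = FALSE,
                           seed = 10000 + s)$truth$nearest_distance_nm, 0)
  expect_lt(abs(median(d) - 289) / 289, 0.05)
})

test_that("camera noise model is seed-stable and optional", {
  sp <- data.frame(channel = 1L, frame = 1L, y_px = 8, x_px = 8,
                   amplitude = 100, sigma_px = 1.3)
  sc <- ground_truth_scene(17, 17, sp, background = 50, shot_noise = TRUE,
                           read_sigma = 3)
  a <- render_scene(sc, seed = 4); b <- render_scene(sc, seed = 4)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, render_scene(sc, seed = 5)$pixels))
  expect_true(all(a$pixels >= 0))
})
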