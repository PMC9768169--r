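test_that("normalization divides by the pre-bleach mean", {
  cv <- normalize_frap(c(80, 120), c(150, 250))
  expect_equal(cv$intensity, c(0.4, 0.6))
  expect_equal(cv$time_s, c(0, 4))
  same <- normalize_frap(rep(200, 5), c(180, 220))
  expect_true(all(same$intensity == 1))
  scaled <- normalize_frap(c(80, 120) * 3, c(150, 250) * 3)
  expect_equal(scaled$intensity, cv$intensity)
  expect_error(normalize_frap(1:3, numeric(0)), "empty")
  expect_error(normalize_frap(1:3, c(0, 0)), "> 0")
})

test_that("noiseless curves are fitted to machine-level accuracy", {
  cv <- simulate_frap_curve(frap_sim_params(0.41, 0.5, 30, dt_s = 4,
                                            n_points = 25))
  ft <- fit_frap(cv)
  expect_true(ft$converged)
  expect_equal(unname(coef(ft)), c(0.41, 0.5, 30), tolerance = 1e-6)
  expect_lt(ft$S, 1e-12)

  # baseline fixed at the true value
  ftf <- fit_frap(cv, baseline = 0.41)
  expect_equal(ftf$tau, 30, tolerance = 1e-6)
  expect_true(ftf$baseline_fixed)
})

test_that("noisy ensembles recover tau and mobile fraction on average", {
  fits <- vapply(1:20, function(i) {
    cv <- simulate_frap_curve(frap_sim_params(0.41, 0.492, 26.3,
                                              noise_sigma = 0.03,
                                              seed = 500 + i))
    ft <- fit_frap(cv)
    c(ft$tau, ft$f_mobile)
  }, c(0, 0))
  expect_lt(abs(mean(fits[1, ]) - 26.3) / 26.3, 0.10)
  expect_lt(abs(mean(fits[2, ]) - 0.492) / 0.492, 0.10)
})

test_that("degenerate constant curves are flagged, not fitted", {
  cv <- data.frame(time_s = (0:9) * 4, intensity = rep(0.41, 10))
  ft <- fit_frap(cv)
  expect_false(ft$converged)
  expect_match(ft$flag, "unidentifiable")
  expect_equal(ft$f_mobile, 0)
  expect_error(fit_frap(cv[1:3, ]), "5 post-bleach")
})

test_that("fitting is invariant to a uniform time shift", {
  cv <- simulate_frap_curve(frap_sim_params(0.3, 0.55, 40, noise_sigma = 0.02,
                                            seed = 77))
  shifted <- cv; shifted$time_s <- shifted$time_s + 120
  expect_equal(coef(fit_frap(cv)), coef(fit_frap(shifted)))
})

test_that("joint baseline recovers a shared generating baseline", {
  mk <- function(f, tau) simulate_frap_curve(
    frap_sim_params(0.41, f, tau, dt_s = 4, n_points = 25))
  jb <- joint_baseline(mk(0.533, 107.4), mk(0.492, 26.3))
  expect_equal(jb$baseline, 0.41, tolerance = 0.011)
  # profile is unimodal on the grid (single local minimum)
  s <- jb$profile$S_total
  drops <- diff(s) < -1e-12
  expect_lte(sum(diff(drops) == 1), 1)
})

test_that("identical curve sets reduce to the single-set minimum", {
  cv <- simulate_frap_curve(frap_sim_params(0.35, 0.5, 50))
  jb <- joint_baseline(cv, cv)
  expect_equal(jb$profile$S_a, jb$profile$S_b)
  single <- vapply(jb$profile$baseline,
                   function(b) fit_frap(cv, baseline = b)$S, 0)
  expect_equal(jb$profile$baseline[which.min(single)], jb$baseline)
})

test_that("grid refinement changes the optimum by at most one step", {
  mk <- function(f, tau) simulate_frap_curve(
    frap_sim_params(0.38, f, tau, dt_s = 4, n_points = 25))
  a <- mk(0.5, 60); b <- mk(0.45, 20)
  coarse <- joint_baseline(a, b, seq(0, 0.8, 0.01))
  fine <- joint_baseline(a, b, seq(max(coarse$baseline - 0.02, 0),
                                   coarse$baseline + 0.02, 0.002))
  expect_lte(abs(fine$baseline - coarse$baseline), 0.01)
  expect_error(joint_baseline(a, b, c(0.1, 0.2)), "3 points")
  expect_error(joint_baseline(list(), b), "non-empty")
})
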