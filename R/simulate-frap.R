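#' FRAP simulation parameters
#'
#' Parameters of a simulated fluorescence-recovery curve following the
#' single-exponential-with-baseline recovery model
#' `I_norm(t) = baseline + f_mobile * (1 - exp(-t / tau))`, where
#' `baseline` is the expected normalized intensity immediately after the
#' bleach, `f_mobile` the mobile fraction and `tau` the recovery time
#' constant.
#'
#' @param baseline expected normalized intensity at t = 0 (0..1).
#' @param f_mobile mobile fraction (0..1); `baseline + f_mobile` may exceed
#'   1 by at most 5 percent (measurement-scale slack).
#' @param tau recovery time constant, seconds, > 0.
#' @param dt_s sampling interval, seconds (default 4).
#' @param n_points number of post-bleach samples.
#' @param noise_sigma SD of additive Gaussian noise on the normalized scale.
#' @param seed optional integer seed.
#' @return Object of class `frap_sim_params`.
#' @export
frap_sim_params <- function(baseline, f_mobile, tau, dt_s = 4,
                            n_points = 25L, noise_sigma = 0, seed = NULL) {
  check_scalar(baseline, "baseline", lower = 0, upper = 1)
  check_scalar(f_mobile, "f_mobile", lower = 0, upper = 1)
  if (baseline + f_mobile > 1.05)
    stop_txspot("baseline + f_mobile must be <= 1.05 (got %.3f)",
                baseline + f_mobile)
  check_scalar(tau, "tau", lower = 0, strict_lower = TRUE)
  check_scalar(dt_s, "dt_s", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  stopifnot(n_points >= 2)
  structure(list(baseline = baseline, f_mobile = f_mobile, tau = tau,
                 dt_s = dt_s, n_points = as.integer(n_points),
                 noise_sigma = noise_sigma, seed = seed),
            class = "frap_sim_params")
}

#' Simulate a normalized FRAP recovery curve
#'
#' Evaluates the exponential recovery model on a regular post-bleach time
#' grid (t = 0 at the first post-bleach frame) and adds optional Gaussian
#' noise.
#'
#' @param params a [frap_sim_params()] object.
#' @return A `frap_curve` data frame with columns `time_s` and `intensity`.
#' @examples
#' simulate_frap_curve(frap_sim_params(0.41, 0.492, 26.3))
#' @export
simulate_frap_curve <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  t <- (seq_len(params$n_points) - 1L) * params$dt_s
  i <- params$baseline + params$f_mobile * (1 - exp(-t / params$tau))
  if (params$noise_sigma > 0)
    i <- i + rnorm(length(t), sd = params$noise_sigma)
  structure(data.frame(time_s = t, intensity = i),
            class = c("frap_curve", "data.frame"))
}
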