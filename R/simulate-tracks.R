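#' Fractional Gaussian noise via circulant embedding
#'
#' Draws `n_series` independent stationary fractional Gaussian noise series
#' of length `n` with Hurst exponent `H` and unit increment variance, using
#' the Davies-Harte circulant-embedding construction (exact target
#' autocovariance).  Used internally to generate sub-diffusive locus
#' displacements; exported because it is independently testable.
#'
#' @param n series length.
#' @param H Hurst exponent in (0, 1).
#' @param n_series number of independent series.
#' @return `n x n_series` matrix of increments.
#' @keywords internal
#' @export
fgn_davies_harte <- function(n, H, n_series = 1L) {
  stopifnot(n >= 1, H > 0, H < 1, n_series >= 1)
  if (abs(H - 0.5) < 1e-12)
    return(matrix(rnorm(n * n_series), n, n_series))
  k <- 0:n
  gamma <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                    abs(k - 1)^(2 * H))
  m <- 2L * n
  circ <- c(gamma[1:n], gamma[n + 1L], rev(gamma[2:n]))
  lambda <- Re(fft(circ))
  if (any(lambda < -1e-8))
    stop_txspot("circulant embedding failed (negative eigenvalue); n=%d H=%g", n, H)
  lambda <- pmax(lambda, 0)
  out <- matrix(0, n, n_series)
  half <- m %/% 2L
  for (j in seq_len(n_series)) {
    v <- complex(length.out = m)
    v[1L] <- sqrt(lambda[1L]) * rnorm(1L)
    v[half + 1L] <- sqrt(lambda[half + 1L]) * rnorm(1L)
    z1 <- rnorm(half - 1L); z2 <- rnorm(half - 1L)
    idx <- 2:half
    v[idx] <- sqrt(lambda[idx] / 2) * complex(real = z1, imaginary = z2)
    v[m + 2L - idx] <- Conj(v[idx])
    x <- Re(fft(v)) / sqrt(m)
    out[, j] <- x[1:n]
  }
  out
}

#' Simulate diffusing locus trajectories
#'
#' Generates 2D trajectories of a chromatin locus undergoing (possibly
#' anomalous) diffusion with ensemble mean squared displacement
#' `MSD(t) = 4 * D_alpha * t^alpha`.  `alpha = 1` gives Brownian motion;
#' `alpha != 1` uses exact fractional Gaussian increments (Hurst exponent
#' `alpha / 2`), so the target power law holds at every lag without ad-hoc
#' rescaling.  Optional i.i.d. Gaussian localization error is added to each
#' recorded position.
#'
#' @param D_alpha generalized diffusion coefficient, um^2 / s^alpha.
#' @param alpha anomalous exponent, 0 < alpha <= 2.
#' @param n_frames frames per track.
#' @param dt_s frame interval, seconds.
#' @param localization_sigma_nm per-axis localization error SD, nm.
#' @param n_tracks number of independent tracks.
#' @param seed optional integer seed.
#' @return Object of class `locus_tracks`: list of `n_frames x 2` matrices
#'   of positions in nm, with attribute `dt_s`.
#' @examples
#' trk <- simulate_locus_track(0.0037, 1, 100, 0.03, n_tracks = 5, seed = 1)
#' @export
simulate_locus_track <- function(D_alpha, alpha, n_frames, dt_s,
                                 localization_sigma_nm = 0,
                                 n_tracks = 1L, seed = NULL) {
  check_scalar(D_alpha, "D_alpha", lower = 0)
  check_scalar(alpha, "alpha", lower = 0, upper = 2, strict_lower = TRUE)
  check_scalar(dt_s, "dt_s", lower = 0, strict_lower = TRUE)
  stopifnot(n_frames >= 2, n_tracks >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_inc <- n_frames - 1L
  # per-axis increment scale: E[(x(t)-x(0))^2] = 2 D t^alpha  (um^2)
  sigma_um <- sqrt(2 * D_alpha * dt_s^alpha)
  make_axis <- function() {
    if (D_alpha == 0) return(matrix(0, n_inc, n_tracks))
    if (abs(alpha - 1) < 1e-12)
      matrix(rnorm(n_inc * n_tracks, sd = sigma_um), n_inc, n_tracks)
    else
      fgn_davies_harte(n_inc, H = alpha / 2, n_series = n_tracks) * sigma_um
  }
  dy <- make_axis(); dx <- make_axis()
  tracks <- vector("list", n_tracks)
  for (j in seq_len(n_tracks)) {
    pos <- cbind(c(0, cumsum(dy[, j])), c(0, cumsum(dx[, j]))) * 1000 # nm
    if (localization_sigma_nm > 0)
      pos <- pos + matrix(rnorm(2L * n_frames, sd = localization_sigma_nm),
                          n_frames, 2L)
    colnames(pos) <- c("y_nm", "x_nm")
    tracks[[j]] <- pos
  }
  structure(tracks, class = "locus_tracks", dt_s = dt_s,
            D_alpha = D_alpha, alpha = alpha)
}

#' @export
print.locus_tracks <- function(x, ...) {
  cat(sprintf("%d simulated locus track(s), %d frames at %.3g s\n",
              length(x), nrow(x[[1L]]), attr(x, "dt_s")))
  invisible(x)
}
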