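#' Mean square change in distance (MSCD)
#'
#' Mobility statistic for a genomic locus that compensates whole-nucleus
#' motion: with `d(t)` the Euclidean distance between the locus and the
#' nuclear centre of mass at frame `t`, the MSCD at lag `dt` is the average
#' of `[d(t) - d(t + dt)]^2` over all valid time pairs.  2D or 3D
#' coordinates are used according to the input dimensionality.
#'
#' @param track numeric matrix of locus positions, one row per frame, 2 or
#'   3 columns (nm).
#' @param centers matrix of the nuclear centre of mass per frame, same
#'   shape as `track`.
#' @param lags integer vector of lags in frames (default all positive lags).
#' @param dt_s frame interval, seconds, used for the lag axis.
#' @return Data frame of class `mscd_curve`: `lag_s`, `mscd` (nm^2), `sem`,
#'   `n`.
#' @export
mscd_curve <- function(track, centers, lags = NULL, dt_s = 1) {
  track <- as.matrix(track); centers <- as.matrix(centers)
  if (nrow(track) < 2) stop_txspot("need at least 2 frames")
  if (!all(dim(track) == dim(centers)))
    stop_txspot("track and centers must be time-aligned")
  d <- sqrt(rowSums((track - centers)^2))
  n <- length(d)
  lags <- lags %||% seq_len(n - 1L)
  out <- lapply(lags, function(k) {
    if (k >= n) return(data.frame(lag_s = k * dt_s, mscd = NA_real_,
                                  sem = NA_real_, n = 0L))
    sq <- (d[seq_len(n - k)] - d[seq_len(n - k) + k])^2
    data.frame(lag_s = k * dt_s, mscd = mean(sq),
               sem = if (length(sq) > 1) sd(sq) / sqrt(length(sq)) else NA_real_,
               n = length(sq))
  })
  out <- do.call(rbind, out)
  class(out) <- c("mscd_curve", "data.frame")
  out
}

#' Average MSCD curves across cells
#'
#' Per-lag mean and SEM across a list of per-cell curves (matched on lag).
#'
#' @param curves list of [mscd_curve()] results.
#' @return Data frame `lag_s`, `mscd`, `sem`, `n_cells`.
#' @export
mscd_average <- function(curves) {
  stopifnot(length(curves) >= 1)
  lags <- sort(unique(unlist(lapply(curves, `[[`, "lag_s"))))
  out <- lapply(lags, function(l) {
    vals <- unlist(lapply(curves, function(cu) cu$mscd[cu$lag_s == l]))
    vals <- vals[is.finite(vals)]
    data.frame(lag_s = l, mscd = mean(vals),
               sem = if (length(vals) > 1) sd(vals) / sqrt(length(vals))
               else NA_real_,
               n_cells = length(vals))
  })
  do.call(rbind, out)
}

#' Time-and-ensemble mean squared displacement
#'
#' Time-averaged MSD per track (all ordered pairs at each lag), then the
#' unweighted ensemble average across tracks.
#'
#' @param tracks a `locus_tracks` object or list of position matrices (nm).
#' @param dt_s frame interval, seconds.
#' @param max_lag_steps largest lag, frames.
#' @return Data frame `lag_s`, `msd_um2`, `n_tracks`.
#' @export
msd_curve <- function(tracks, dt_s = NULL, max_lag_steps = 66L) {
  dt_s <- dt_s %||% attr(tracks, "dt_s")
  stopifnot(!is.null(dt_s), length(tracks) >= 1)
  n_min <- min(vapply(tracks, nrow, 0L))
  lags <- seq_len(min(max_lag_steps, n_min - 1L))
  per_track <- vapply(tracks, function(p) {
    p <- as.matrix(p) / 1000  # nm -> um
    vapply(lags, function(k) {
      dis <- p[seq_len(nrow(p) - k) + k, , drop = FALSE] -
        p[seq_len(nrow(p) - k), , drop = FALSE]
      mean(rowSums(dis^2))
    }, 0)
  }, numeric(length(lags)))
  per_track <- matrix(per_track, nrow = length(lags))
  data.frame(lag_s = lags * dt_s, msd_um2 = rowMeans(per_track),
             n_tracks = length(tracks))
}

#' Fit the anomalous-diffusion model to an ensemble MSD
#'
#' Fits `MSD(t) = 4 * D_alpha * t^alpha` to the time-and-ensemble-averaged
#' MSD over lags up to `max_lag_steps`.  The default fit is linear least
#' squares on `log(MSD)` vs `log(t)` (equal weights), which linearizes the
#' two-parameter power law; `method = "linear"` performs nonlinear least
#' squares on the natural scale instead.  No localization-noise offset is
#' fitted (two-parameter model); this is a documented bias source when
#' localization error is appreciable.
#'
#' @param tracks a `locus_tracks` object or list of position matrices
#'   (nm), or a precomputed MSD curve (data frame with `lag_s`,
#'   `msd_um2`).
#' @param dt_s frame interval, seconds.
#' @param max_lag_steps fit window in lag steps (default 66).
#' @param method `"loglog"` (default) or `"linear"`.
#' @return Object of class `msd_fit`: list with `D_alpha` (um^2/s^alpha),
#'   `alpha`, `msd` (the curve), `residual` (RSS on the fitted scale),
#'   `method`, `flag`.
#' @export
msd_fit <- function(tracks, dt_s = NULL, max_lag_steps = 66L,
                    method = c("loglog", "linear")) {
  method <- match.arg(method)
  if (is.data.frame(tracks) &&
      all(c("lag_s", "msd_um2") %in% names(tracks))) {
    curve <- tracks[seq_len(min(nrow(tracks), max_lag_steps)), ,
                    drop = FALSE]
  } else {
    dt_s <- dt_s %||% attr(tracks, "dt_s")
    curve <- msd_curve(tracks, dt_s = dt_s, max_lag_steps = max_lag_steps)
  }
  flag <- NA_character_
  if (all(curve$msd_um2 <= 0)) {
    fit <- list(D_alpha = 0, alpha = NA_real_, residual = 0,
                flag = "all-zero MSD: alpha undefined")
  } else if (method == "loglog") {
    sel <- curve$msd_um2 > 0
    lf <- lm(log(msd_um2) ~ log(lag_s), data = curve[sel, ])
    fit <- list(D_alpha = exp(coef(lf)[[1L]]) / 4,
                alpha = coef(lf)[[2L]],
                residual = sum(residuals(lf)^2), flag = flag)
  } else {
    nf <- minpack.lm::nlsLM(msd_um2 ~ 4 * D * lag_s^a, data = curve,
                            start = list(D = max(curve$msd_um2[1L] /
                                                   (4 * curve$lag_s[1L]),
                                                 1e-8), a = 1),
                            lower = c(0, 1e-3), upper = c(Inf, 2))
    fit <- list(D_alpha = coef(nf)[["D"]], alpha = coef(nf)[["a"]],
                residual = sum(residuals(nf)^2), flag = flag)
  }
  structure(list(D_alpha = fit$D_alpha, alpha = fit$alpha, msd = curve,
                 residual = fit$residual, method = method,
                 max_lag_steps = max_lag_steps, flag = fit$flag),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat("Anomalous-diffusion MSD fit: MSD(t) = 4 D t^alpha\n")
  cat(sprintf("  D_alpha = %.4g um^2/s^alpha, alpha = %.3f (%s fit, %d lags)\n",
              x$D_alpha, x$alpha, x$method, nrow(x$msd)))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(D_alpha = object$D_alpha, alpha = object$alpha)
}

#' @export
predict.msd_fit <- function(object, lag_s = NULL, ...) {
  lag_s <- lag_s %||% object$msd$lag_s
  4 * object$D_alpha * lag_s^object$alpha
}

#' @export
plot.msd_fit <- function(x, ...) {
  plot(x$msd$lag_s, x$msd$msd_um2, log = "xy", xlab = "lag (s)",
       ylab = expression(MSD ~ (mu * m^2)), pch = 16, ...)
  lines(x$msd$lag_s, predict(x), col = 2)
  invisible(x)
}
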