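#' Detect fluorescent spots and refine centres to sub-pixel accuracy
#'
#' Candidate spots are local intensity maxima (8-neighbourhood) above a
#' threshold; exact ties within a plateau are resolved to the lowest
#' `(row, col)` position, so detection is deterministic.  Each candidate is
#' refined by least-squares fitting of a 2D isotropic Gaussian plus a
#' constant offset within a square window centred on the candidate pixel;
#' candidates whose window would cross the image border are dropped with a
#' warning (padded fits would bias the localization), and fits that fail to
#' converge fall back to the background-subtracted centroid with
#' `fit_ok = FALSE`.
#'
#' @param image 2D numeric matrix (a preprocessed plane) or an
#'   [image_stack()] (first plane used).
#' @param expected_diameter_px approximate spot diameter, odd, >= 3; sets
#'   the Gaussian starting sigma.
#' @param threshold absolute intensity a local maximum must exceed; ignored
#'   when `max_candidates` is given.
#' @param max_candidates keep only the brightest `n` maxima.
#' @param roi optional `(y, x)` centre (0-based px) of an anchored
#'   analysis window of side `roi_size_px`; detection is then restricted to
#'   that window and the window mean is reported (used as the fold-change
#'   reference in proximity state calls).
#' @param roi_size_px side of the anchored window (default 19).
#' @param fit_window_px side of the Gaussian refinement window (odd).
#' @param min_separation_px minimum distance between accepted candidates;
#'   weaker maxima within this distance of a stronger one are suppressed
#'   (camera noise can split one spot into several adjacent maxima).
#' @return Data frame of class `spot_table`: `y_px`, `x_px` (sub-pixel,
#'   0-based), `sigma_px`, `amplitude`, `offset`, `peak`, `fit_ok`.
#'   When `roi` is given, attribute `roi_mean` carries the window mean.
#' @export
detect_and_refine <- function(image, expected_diameter_px = 5L,
                              threshold = NULL, max_candidates = NULL,
                              roi = NULL, roi_size_px = 19L,
                              fit_window_px = 11L,
                              min_separation_px = expected_diameter_px) {
  if (inherits(image, "image_stack")) image <- stack_plane(image)
  stopifnot(is.matrix(image))
  if (expected_diameter_px < 3 || expected_diameter_px %% 2 == 0)
    stop_txspot("expected_diameter_px must be odd and >= 3")
  if (fit_window_px %% 2 == 0) stop_txspot("fit_window_px must be odd")

  roi_mean <- NA_real_
  offset_yx <- c(0, 0)
  if (!is.null(roi)) {
    half <- (roi_size_px - 1L) %/% 2L
    r0 <- round(roi[1L]) + 1L; c0 <- round(roi[2L]) + 1L
    ys <- max(1L, r0 - half):min(nrow(image), r0 + half)
    xs <- max(1L, c0 - half):min(ncol(image), c0 + half)
    image_roi <- image[ys, xs, drop = FALSE]
    roi_mean <- mean(image_roi)
    offset_yx <- c(ys[1L] - 1L, xs[1L] - 1L)
    image_full <- image
    image <- image_roi
  } else image_full <- image

  if (is.null(threshold) && is.null(max_candidates))
    threshold <- mean(image) + 5 * sd(image)
  cand <- local_maxima(image, threshold = threshold %||% -Inf)
  if (nrow(cand) > 1) {
    # non-maximum suppression: noise can split one spot into several
    # nearby maxima; keep only the brightest within min_separation_px
    ord <- order(-cand$value, cand$row, cand$col)
    cand <- cand[ord, , drop = FALSE]
    kept <- 1L
    for (i in 2:nrow(cand)) {
      d2 <- (cand$row[kept] - cand$row[i])^2 +
        (cand$col[kept] - cand$col[i])^2
      if (all(d2 >= min_separation_px^2)) kept <- c(kept, i)
    }
    cand <- cand[kept, , drop = FALSE]
  }
  if (nrow(cand) && !is.null(max_candidates))
    cand <- cand[seq_len(min(max_candidates, nrow(cand))), , drop = FALSE]

  half_w <- (fit_window_px - 1L) %/% 2L
  sigma0 <- expected_diameter_px / 4
  rows <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(cand))) {
    # window positions in the full image
    r <- cand$row[i] + offset_yx[1L]
    c <- cand$col[i] + offset_yx[2L]
    if (r - half_w < 1L || r + half_w > nrow(image_full) ||
        c - half_w < 1L || c + half_w > ncol(image_full)) {
      n_dropped <- n_dropped + 1L
      next
    }
    win <- image_full[(r - half_w):(r + half_w), (c - half_w):(c + half_w)]
    fit <- fit_gaussian_2d(win, sigma0 = sigma0,
                           center0 = c(half_w, half_w),
                           center_bound_px = expected_diameter_px / 2 + 0.5)
    rows[[length(rows) + 1L]] <- data.frame(
      y_px = r - 1L - half_w + fit$y0,
      x_px = c - 1L - half_w + fit$x0,
      sigma_px = fit$sigma, amplitude = fit$amplitude,
      offset = fit$offset, peak = cand$value[i], fit_ok = fit$converged)
  }
  if (n_dropped > 0)
    warning(sprintf("%d candidate(s) dropped: refinement window crossed the border",
                    n_dropped))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(y_px = numeric(), x_px = numeric(), sigma_px = numeric(),
               amplitude = numeric(), offset = numeric(), peak = numeric(),
               fit_ok = logical())
  class(out) <- c("spot_table", "data.frame")
  attr(out, "roi_mean") <- roi_mean
  out
}

#' Local maxima of a 2D image
#'
#' A pixel is reported when it is >= all 8 neighbours and strictly above
#' `threshold`; within an exact-tie plateau only the lexicographically
#' smallest `(row, col)` pixel is kept.
#'
#' @param image numeric matrix.
#' @param threshold strict lower bound on the maximum value.
#' @return Data frame `row`, `col` (1-based), `value`.
#' @export
local_maxima <- function(image, threshold = -Inf) {
  ny <- nrow(image); nx <- ncol(image)
  if (ny < 3 || nx < 3)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- image
  is_max <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
    is_max <- is_max & (image >= nb)
  }
  is_max <- is_max & (image > threshold)
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  df <- data.frame(row = idx[, 1L], col = idx[, 2L],
                   value = image[idx])
  df <- df[order(df$row, df$col), , drop = FALSE]
  # collapse adjacent equal-valued maxima (plateaus) to the first position
  keep <- rep(TRUE, nrow(df))
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) {
      if (!keep[i]) next
      earlier <- which(keep[seq_len(i - 1L)])
      same <- earlier[abs(df$row[earlier] - df$row[i]) <= 1 &
                        abs(df$col[earlier] - df$col[i]) <= 1 &
                        df$value[earlier] == df$value[i]]
      if (length(same)) keep[i] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Least-squares 2D isotropic Gaussian fit
#'
#' Fits `offset + A * exp(-((y - y0)^2 + (x - x0)^2) / (2 sigma^2))` to a
#' square window by Levenberg-Marquardt least squares.  Coordinates are
#' relative to the window's first pixel (0-based).  On non-convergence the
#' background-subtracted centroid is returned with `converged = FALSE`.
#'
#' @param win numeric matrix (the fit window).
#' @param sigma0 starting sigma, px.
#' @param center0 starting centre `(y, x)` in window coordinates (default
#'   the brightest pixel).
#' @param center_bound_px maximum distance (per axis) the fitted centre may
#'   move from `center0`; keeps the fit from latching onto a brighter
#'   neighbouring spot inside the window.
#' @return List: `y0`, `x0`, `sigma`, `amplitude`, `offset`, `converged`.
#' @export
fit_gaussian_2d <- function(win, sigma0 = 1.5, center0 = NULL,
                            center_bound_px = Inf) {
  ny <- nrow(win); nx <- ncol(win)
  yy <- rep(0:(ny - 1L), nx)
  xx <- rep(0:(nx - 1L), each = ny)
  v <- as.numeric(win)
  pk <- center0 %||% (arrayInd(which.max(win), dim(win)) - 1L)
  start <- c(off = min(v), A = max(v) - min(v),
             y0 = pk[1L], x0 = pk[2L], s = sigma0)
  res_fun <- function(p) {
    v - (p[1L] + p[2L] * exp(-((yy - p[3L])^2 + (xx - p[4L])^2) /
                               (2 * p[5L]^2)))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = res_fun,
                       lower = c(-Inf, 0,
                                 max(-1, pk[1L] - center_bound_px),
                                 max(-1, pk[2L] - center_bound_px), 0.2),
                       upper = c(Inf, Inf,
                                 min(ny, pk[1L] + center_bound_px),
                                 min(nx, pk[2L] + center_bound_px),
                                 max(ny, nx)),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$info %in% 1:4 && fit$par[["s"]] > 0
  if (ok) {
    p <- fit$par
    list(y0 = p[["y0"]], x0 = p[["x0"]], sigma = p[["s"]],
         amplitude = p[["A"]], offset = p[["off"]], converged = TRUE)
  } else {
    w <- pmax(v - min(v), 0)
    if (sum(w) == 0) w <- rep(1, length(v))
    list(y0 = sum(w * yy) / sum(w), x0 = sum(w * xx) / sum(w),
         sigma = sigma0, amplitude = max(v) - min(v), offset = min(v),
         converged = FALSE)
  }
}
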