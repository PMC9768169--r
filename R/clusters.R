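#' Nearest regulatory-factor cluster distance
#'
#' 2D Euclidean distance, in nm, from a DNA-label anchor spot to the
#' nearest factor cluster in the same cell (sub-pixel pixel coordinates
#' scaled by the pixel size).
#'
#' @param anchor list or one-row data frame with `y_px`, `x_px`.
#' @param clusters data frame of cluster centres (`y_px`, `x_px`); may be
#'   empty.
#' @param pixel_size_nm calibration (default 130).
#' @param state optional ON/OFF state label carried into the record.
#' @param cluster_intensity optional vector of cluster disk-mean
#'   intensities aligned with `clusters`.
#' @return One-row data frame: `distance_nm` (`NA` with `reason` when no
#'   clusters), `nearest_y_px`, `nearest_x_px`, `nearest_intensity`,
#'   `state`.
#' @export
nearest_distance <- function(anchor, clusters, pixel_size_nm = 130,
                             state = NA_character_,
                             cluster_intensity = NULL) {
  if (is.null(clusters) || nrow(clusters) == 0) {
    return(data.frame(distance_nm = NA_real_, nearest_y_px = NA_real_,
                      nearest_x_px = NA_real_,
                      nearest_intensity = NA_real_, state = state,
                      reason = "no clusters detected"))
  }
  d <- sqrt((clusters$y_px - anchor$y_px)^2 +
              (clusters$x_px - anchor$x_px)^2) * pixel_size_nm
  i <- which.min(d)
  data.frame(distance_nm = d[i], nearest_y_px = clusters$y_px[i],
             nearest_x_px = clusters$x_px[i],
             nearest_intensity = if (is.null(cluster_intensity)) NA_real_
             else cluster_intensity[i],
             state = state, reason = NA_character_)
}

#' Distance-stratified or state-stratified group comparison
#'
#' Splits cluster-distance records into two groups — either short vs long
#' distance around a threshold (boundary values go to the short group) or
#' ON vs OFF state — and compares a chosen variable between the groups
#' with a two-sided Wilcoxon rank-sum test.  For combined n <= 20 the
#' exact permutation distribution of the rank sum (midranks for ties) is
#' enumerated; larger samples use the normal approximation with tie
#' correction.
#'
#' @param records data frame with `distance_nm`, `state` and the value
#'   column.
#' @param variable name of the compared column (default `"distance_nm"`).
#' @param grouping `"distance"` (short/long around the threshold, applied
#'   to `distance_nm`) or `"state"` (ON/OFF).
#' @param distance_threshold_nm stratification threshold (default 350).
#' @return Object of class `stratified_comparison`: per-group `summary`
#'   (n, median, IQR), `p_value`, `method`, `boundary` note.  When a group
#'   is empty the result carries `p_value = NA` and a reason instead of
#'   failing.
#' @export
stratified_comparison <- function(records, variable = "distance_nm",
                                  grouping = c("distance", "state"),
                                  distance_threshold_nm = 350) {
  grouping <- match.arg(grouping)
  stopifnot(variable %in% names(records))
  v <- records[[variable]]
  grp <- if (grouping == "distance") {
    ifelse(records$distance_nm <= distance_threshold_nm, "short", "long")
  } else records$state
  ok <- is.finite(v) & !is.na(grp)
  v <- v[ok]; grp <- grp[ok]
  levels_ <- if (grouping == "distance") c("short", "long") else c("ON", "OFF")
  a <- v[grp == levels_[1L]]; b <- v[grp == levels_[2L]]
  summ <- do.call(rbind, lapply(seq_along(levels_), function(i) {
    g <- if (i == 1L) a else b
    data.frame(group = levels_[i], n = length(g),
               median = if (length(g)) median(g) else NA_real_,
               q25 = if (length(g)) quantile(g, 0.25, names = FALSE) else NA_real_,
               q75 = if (length(g)) quantile(g, 0.75, names = FALSE) else NA_real_)
  }))
  if (length(a) == 0 || length(b) == 0) {
    return(structure(list(summary = summ, p_value = NA_real_,
                          method = "none",
                          reason = "one group empty: no test performed",
                          boundary = "threshold assigned to short group"),
                     class = "stratified_comparison"))
  }
  if (length(a) + length(b) <= 20) {
    p <- rank_sum_exact(a, b)
    method <- "exact permutation rank-sum"
  } else {
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                      correct = TRUE)$p.value)
    method <- "normal approximation with tie correction"
  }
  structure(list(summary = summ, p_value = p, method = method,
                 reason = NA_character_,
                 boundary = "threshold assigned to short group"),
            class = "stratified_comparison")
}

#' @export
print.stratified_comparison <- function(x, ...) {
  print(x$summary)
  if (is.na(x$p_value)) cat("No test:", x$reason, "\n")
  else cat(sprintf("Two-sided rank-sum p = %.4g (%s)\n", x$p_value, x$method))
  invisible(x)
}

#' Exact two-sided rank-sum p-value by enumeration
#'
#' Enumerates all assignments of the pooled observations (midranks for
#' ties) to the two groups and returns the two-sided probability of a rank
#' sum at least as extreme as observed.  Intended for small samples
#' (combined n <= 20).
#'
#' @param a,b numeric vectors.
#' @return Two-sided p-value.
#' @export
rank_sum_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  w_obs <- sum(r[seq_len(n_a)])
  e_w <- n_a * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  w_all <- colSums(matrix(r[combos], nrow = n_a))
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
}

#' Averaged cluster image and FWHM size
#'
#' Averages equally sized square regions of interest centred on detected
#' clusters pixel-wise, fits a 2D circular Gaussian plus constant offset
#' to the mean image, and reports the full width at half maximum
#' `FWHM = 2 sqrt(2 ln 2) sigma` in pixels and nm.
#'
#' @param rois list of equally sized numeric matrices (e.g. 19x19 windows),
#'   or a 3D array `(n, y, x)`.
#' @param pixel_size_nm calibration (default 130).
#' @return List: `mean_image`, `sigma_px`, `fwhm_px`, `fwhm_nm`,
#'   `center_px` (0-based, within the ROI), `converged`.
#' @export
cluster_fwhm <- function(rois, pixel_size_nm = 130) {
  if (is.array(rois) && length(dim(rois)) == 3L)
    rois <- lapply(seq_len(dim(rois)[1L]), function(i)
      matrix(rois[i, , ], dim(rois)[2L], dim(rois)[3L]))
  stopifnot(length(rois) >= 1)
  d <- dim(rois[[1L]])
  for (r in rois) if (!all(dim(r) == d))
    stop_txspot("all ROIs must have the same shape")
  mean_img <- Reduce(`+`, rois) / length(rois)
  fit <- fit_gaussian_2d(mean_img, sigma0 = max(d) / 8)
  fwhm_px <- 2 * sqrt(2 * log(2)) * fit$sigma
  list(mean_image = mean_img, sigma_px = fit$sigma, fwhm_px = fwhm_px,
       fwhm_nm = fwhm_px * pixel_size_nm,
       center_px = c(fit$y0, fit$x0), converged = fit$converged)
}
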