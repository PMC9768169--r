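#' Transcription ON/OFF state from relative spot intensity
#'
#' Threshold rules for calling the transcriptional state of a locus from
#' the relative intensity (spot disk mean / nuclear mean) of the nascent-RNA
#' reporter channel:
#'
#' * `snapshot` — a single time point is ON when its relative intensity is
#'   `>= threshold` (default 3, the valley of the relative-intensity
#'   histogram in snapshot imaging).
#' * `trace` — a time-lapse is ON when transcription is observed at least
#'   once, i.e. any frame's relative intensity is `>= threshold` (default
#'   5, the corresponding histogram-valley value for z-stack time-lapse
#'   imaging).
#'
#' Boundary convention: "3 or higher" means `>=`.
#'
#' @param values relative intensity value(s); a single value in snapshot
#'   mode, a vector over frames in trace mode.
#' @param mode `"snapshot"` or `"trace"`.
#' @param threshold override the rule's default threshold.
#' @return A `state_call` object: list with `state` (`"ON"`/`"OFF"`),
#'   `rule`, `threshold` and `support` (the measurement that decided the
#'   call).
#' @examples
#' classify_snapshot_or_trace(3.2, "snapshot")$state  # "ON"
#' classify_snapshot_or_trace(c(1, 2, 6, 1), "trace")$state  # "ON"
#' @export
classify_snapshot_or_trace <- function(values,
                                       mode = c("snapshot", "trace"),
                                       threshold = NULL) {
  mode <- match.arg(mode)
  if (length(values) == 0) stop_txspot("empty trace")
  if (!all(is.finite(values))) stop_txspot("values must be finite")
  if (mode == "snapshot" && length(values) != 1L)
    stop_txspot("snapshot mode takes a single value")
  threshold <- threshold %||% if (mode == "snapshot") 3 else 5
  on <- any(values >= threshold)
  state_call(state = if (on) "ON" else "OFF", rule = mode,
             threshold = c(relative_intensity = threshold),
             support = list(max_relative_intensity = max(values)))
}

#' Transcription state from regulatory-factor frame geometry
#'
#' Proximity rule for anchored regulatory-factor imaging: the locus is ON
#' in a frame when any nascent-RNA (MCP) spot lies within
#' `max_distance_nm` of the DNA-label (mTetR) anchor spot *and* has a disk
#' mean intensity strictly greater than `min_fold` times the reference mean
#' (by default the mean of the 19x19 analysis window centred on the
#' anchor; set `reference = "nucleus"` semantics by passing the nuclear
#' mean instead).
#'
#' Boundary conventions: "within 390 nm" means `<=`; "greater than
#' two-fold" is strict `>`.
#'
#' @param anchor list or one-row data frame with `y_px`, `x_px` (sub-pixel,
#'   0-based) of the anchor spot.
#' @param mcp_spots data frame of MCP spots (`y_px`, `x_px`, `disk_mean`);
#'   may be empty.
#' @param reference_mean fold-change reference intensity (ROI mean of the
#'   anchored window, or the nuclear mean).
#' @param max_distance_nm proximity threshold (default 390).
#' @param min_fold fold-change threshold (default 2).
#' @param pixel_size_nm calibration (default 130).
#' @return A `state_call` object (rule `"rf_proximity"`).
#' @export
classify_rf_frame <- function(anchor, mcp_spots, reference_mean,
                              max_distance_nm = 390, min_fold = 2,
                              pixel_size_nm = 130) {
  if (is.null(anchor) || length(anchor$y_px) == 0)
    stop_txspot("missing anchor spot")
  check_scalar(reference_mean, "reference_mean", lower = 0,
               strict_lower = TRUE)
  if (is.null(mcp_spots) || nrow(mcp_spots) == 0) {
    return(state_call("OFF", "rf_proximity",
                      c(distance_nm = max_distance_nm, fold = min_fold),
                      support = list(distance_nm = NA_real_,
                                     fold = NA_real_)))
  }
  d_nm <- sqrt((mcp_spots$y_px - anchor$y_px)^2 +
                 (mcp_spots$x_px - anchor$x_px)^2) * pixel_size_nm
  fold <- mcp_spots$disk_mean / reference_mean
  ok <- d_nm <= max_distance_nm & fold > min_fold
  best <- if (any(ok)) which(ok)[which.min(d_nm[which(ok)])] else
    which.min(d_nm)
  state_call(state = if (any(ok)) "ON" else "OFF", rule = "rf_proximity",
             threshold = c(distance_nm = max_distance_nm, fold = min_fold),
             support = list(distance_nm = d_nm[best], fold = fold[best]))
}

state_call <- function(state, rule, threshold, support) {
  structure(list(state = state, rule = rule, threshold = threshold,
                 support = support),
            class = "state_call")
}

#' @export
print.state_call <- function(x, ...) {
  cat(sprintf("State call: %s (rule %s; %s)\n", x$state, x$rule,
              paste(names(x$threshold), signif(x$threshold, 4),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Histogram-valley threshold
#'
#' Re-derives an intensity threshold as the kernel-density minimum between
#' the first two modes of a relative-intensity distribution (the package's
#' fixed rule thresholds remain the defaults; this is an audit tool).
#'
#' @param values numeric vector of relative intensities.
#' @param bw kernel bandwidth passed to [stats::density()].
#' @return The abscissa of the valley, or `NA` when the density has fewer
#'   than two modes.
#' @export
intensity_valley <- function(values, bw = "nrd0") {
  d <- density(values, bw = bw)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2) return(NA_real_)
  span <- peaks[1L]:peaks[2L]
  d$x[span[which.min(y[span])]]
}
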