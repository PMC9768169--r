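#' Image preprocessing pipeline
#'
#' Applies an ordered list of standard preprocessing steps to an
#' [image_stack()], mirroring the usual ImageJ-style workflow for live-cell
#' spot imaging.  Supported steps (each a `list(op = ..., ...)`):
#'
#' * `median` — 2D median filter, `radius` pixels (applied per plane).
#' * `gaussian` — 2D Gaussian blur, `sigma` pixels (per plane).
#' * `rolling_ball` — rolling-ball background subtraction of the stated
#'   `radius`, realized as a grayscale morphological opening with a disk
#'   structuring element; the opened background is subtracted and the
#'   result clipped at 0.
#' * `max_project` / `avg_project` — z projection (requires a z axis of
#'   length > 1).
#' * `bleach_correct` — simple-ratio bleach correction: each frame is
#'   rescaled so its mean within `mask` (logical matrix; default the whole
#'   frame) equals the first frame's mean.
#' * `drift_correct` — translational drift correction: per-frame integer
#'   shift relative to frame 1 estimated by FFT phase correlation and
#'   undone (vacated pixels filled with 0).
#'
#' Applied steps are recorded in the stack's `provenance`.
#'
#' @param stack an [image_stack()].
#' @param steps list of step descriptors, applied in order.
#' @return The processed [image_stack()].
#' @examples
#' st <- image_stack(matrix(100, 32, 32))
#' out <- preprocess(st, list(list(op = "rolling_ball", radius = 5)))
#' all(out$pixels == 0)  # flat background fully removed
#' @export
preprocess <- function(stack, steps) {
  stopifnot(inherits(stack, "image_stack"))
  for (step in steps) {
    op <- step$op
    if (is.null(op)) stop_txspot("each step needs an 'op' field")
    stack <- switch(op,
      median = apply_per_plane(stack, function(m)
        median_filter_2d(m, need_radius(step)), step),
      gaussian = apply_per_plane(stack, function(m)
        gaussian_filter_2d(m, need_pos(step, "sigma")), step),
      rolling_ball = apply_per_plane(stack, function(m)
        rolling_ball_subtract(m, need_radius(step)), step),
      max_project = z_project(stack, max, step),
      avg_project = z_project(stack, mean, step),
      bleach_correct = bleach_correct(stack, step$mask, step),
      drift_correct = drift_correct(stack, step),
      stop_txspot("unknown preprocessing step '%s'", op))
  }
  stack
}

need_radius <- function(step) need_pos(step, "radius")

need_pos <- function(step, field) {
  v <- step[[field]]
  if (is.null(v) || !is.numeric(v) || v <= 0)
    stop_txspot("step '%s' requires %s > 0", step$op, field)
  v
}

record_step <- function(stack, step) {
  stack$provenance <- c(stack$provenance,
                        list(step[setdiff(names(step), "mask")]))
  stack
}

apply_per_plane <- function(stack, fun, step) {
  ax <- strsplit(stack$axes, "")[[1L]]
  px <- stack$pixels
  for (t in seq_len(n_frames(stack))) {
    for (z in seq_len(n_slices(stack))) {
      m <- fun(stack_plane(stack, t, z))
      px <- assign_plane(px, ax, t, z, m)
    }
  }
  stack$pixels <- px
  record_step(stack, step)
}

assign_plane <- function(px, ax, t, z, m) {
  idx <- rep(list(quote(expr = )), length(ax)); names(idx) <- ax
  if ("t" %in% ax) idx[["t"]] <- t
  if ("z" %in% ax) idx[["z"]] <- z
  do.call(`[<-`, c(list(px), unname(idx), list(value = m)))
}

median_filter_2d <- function(m, radius) {
  hi <- max(m)
  if (hi <= 0) return(m)
  out <- EBImage::medianFilter(m / hi, size = as.integer(radius)) * hi
  matrix(out, nrow(m), ncol(m))
}

gaussian_filter_2d <- function(m, sigma) {
  matrix(EBImage::gblur(m, sigma = sigma), nrow(m), ncol(m))
}

rolling_ball_subtract <- function(m, radius) {
  hi <- max(m)
  if (hi <= 0) return(m * 0)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- EBImage::opening(m / hi, brush) * hi
  pmax(m - matrix(bg, nrow(m), ncol(m)), 0)
}

z_project <- function(stack, fun, step) {
  ax <- strsplit(stack$axes, "")[[1L]]
  if (!("z" %in% ax) || n_slices(stack) <= 1L)
    stop_txspot("projection requires a z axis of length > 1")
  nt <- n_frames(stack)
  ny <- dim(stack$pixels)[match("y", ax)]
  nx <- dim(stack$pixels)[match("x", ax)]
  if ("t" %in% ax) {
    out <- array(0, dim = c(nt, ny, nx))
    for (t in seq_len(nt)) {
      acc <- array(0, dim = c(n_slices(stack), ny, nx))
      for (z in seq_len(n_slices(stack))) acc[z, , ] <- stack_plane(stack, t, z)
      out[t, , ] <- apply(acc, c(2L, 3L), fun)
    }
    new <- image_stack(out, axes = "tyx", pixel_size_nm = stack$pixel_size_nm,
                       frame_interval_s = stack$frame_interval_s,
                       channel = stack$channel)
  } else {
    acc <- array(0, dim = c(n_slices(stack), ny, nx))
    for (z in seq_len(n_slices(stack))) acc[z, , ] <- stack_plane(stack, 1L, z)
    new <- image_stack(apply(acc, c(2L, 3L), fun), axes = "yx",
                       pixel_size_nm = stack$pixel_size_nm,
                       frame_interval_s = stack$frame_interval_s,
                       channel = stack$channel)
  }
  new$provenance <- stack$provenance
  record_step(new, step)
}

bleach_correct <- function(stack, mask, step) {
  if (n_frames(stack) < 2L)
    stop_txspot("bleach correction requires a time axis")
  ref <- NULL
  for (t in seq_len(n_frames(stack))) {
    for (z in seq_len(n_slices(stack))) {
      m <- stack_plane(stack, t, z)
      sel <- if (is.null(mask)) rep(TRUE, length(m)) else as.logical(mask)
      mu <- mean(m[sel])
      if (t == 1L && z == 1L) ref <- mu
      if (mu > 0)
        stack$pixels <- assign_plane(stack$pixels,
                                     strsplit(stack$axes, "")[[1L]],
                                     t, z, m * ref / mu)
    }
  }
  record_step(stack, step)
}

# integer-pixel translational registration against frame 1
drift_correct <- function(stack, step) {
  if (n_frames(stack) < 2L)
    stop_txspot("drift correction requires a time axis")
  ax <- strsplit(stack$axes, "")[[1L]]
  ref <- drift_reference(stack, 1L)
  shifts <- matrix(0L, n_frames(stack), 2L)
  for (t in 2L:n_frames(stack)) {
    shifts[t, ] <- phase_correlate(ref, drift_reference(stack, t))
    for (z in seq_len(n_slices(stack))) {
      m <- stack_plane(stack, t, z)
      stack$pixels <- assign_plane(stack$pixels, ax, t, z,
                                   shift_image(m, -shifts[t, 1L],
                                               -shifts[t, 2L]))
    }
  }
  stack <- record_step(stack, step)
  attr(stack, "drift_shifts") <- shifts
  stack
}

drift_reference <- function(stack, t) {
  if (n_slices(stack) == 1L) return(stack_plane(stack, t, 1L))
  acc <- stack_plane(stack, t, 1L)
  for (z in 2L:n_slices(stack)) acc <- pmax(acc, stack_plane(stack, t, z))
  acc
}

# estimate integer (dy, dx) such that moving = shift(ref, dy, dx)
phase_correlate <- function(ref, moving) {
  fa <- fft(ref); fb <- fft(moving)
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE))
  k <- arrayInd(which.max(cc), dim(cc)) - 1L
  dy <- k[1L]; dx <- k[2L]
  if (dy > nrow(ref) / 2) dy <- dy - nrow(ref)
  if (dx > ncol(ref) / 2) dx <- dx - ncol(ref)
  c(-dy, -dx)
}

shift_image <- function(m, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)); xs <- seq_len(ncol(m))
  ys_src <- ys - dy; xs_src <- xs - dx
  ok_y <- ys_src >= 1 & ys_src <= nrow(m)
  ok_x <- xs_src >= 1 & xs_src <= ncol(m)
  out[ys[ok_y], xs[ok_x]] <- m[ys_src[ok_y], xs_src[ok_x]]
  out
}
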