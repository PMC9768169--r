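#' Measure labelled nuclei
#'
#' Computes per-nucleus intensity statistics and the intensity-weighted
#' centre of mass from a 2D image plane and a label mask.  Externally
#' produced label masks (e.g. from a dedicated segmentation tool) are the
#' first-class input; `masks = "auto"` falls back to a simple threshold
#' segmentation (Otsu threshold, hole filling, minimum-area filter) for
#' synthetic or high-contrast data.
#'
#' @param image an [image_stack()] or a 2D numeric matrix.
#' @param masks integer label matrix (0 = background), or `"auto"`.
#' @param min_area_px minimum object area kept by the auto fallback.
#' @return Data frame with one row per label: `label`, `n_pixels`, `mean`,
#'   `sd` (the nuclear intensity SD used by SNR calculations), `com_y_nm`,
#'   `com_x_nm` (intensity-weighted centre of mass, nm).
#' @export
measure_nuclei <- function(image, masks = "auto", min_area_px = 50) {
  px_nm <- 130
  if (inherits(image, "image_stack")) {
    px_nm <- image$pixel_size_nm
    image <- stack_plane(image)
  }
  stopifnot(is.matrix(image))
  if (identical(masks, "auto")) masks <- auto_segment(image, min_area_px)
  if (!is.matrix(masks) || !all(dim(masks) == dim(image)))
    stop_txspot("mask/image shape mismatch")
  labels <- sort(unique(masks[masks > 0]))
  if (length(labels) == 0) stop_txspot("empty label image (no nuclei)")
  out <- lapply(labels, function(lb) {
    sel <- masks == lb
    v <- image[sel]
    idx <- which(sel, arr.ind = TRUE) - 1L  # 0-based pixel coords
    w <- if (sum(v) > 0) v / sum(v) else rep(1 / length(v), length(v))
    data.frame(label = lb, n_pixels = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0,
               com_y_nm = sum(w * idx[, 1L]) * px_nm,
               com_x_nm = sum(w * idx[, 2L]) * px_nm)
  })
  do.call(rbind, out)
}

# Otsu threshold + hole filling + small-object removal
auto_segment <- function(image, min_area_px) {
  hi <- max(image)
  if (hi <= 0) stop_txspot("cannot auto-segment a non-positive image")
  thr <- EBImage::otsu(EBImage::Image(image / hi), range = c(0, 1))
  bw <- EBImage::fillHull(EBImage::Image(image / hi > thr))
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  tab <- table(lab[lab > 0])
  drop <- as.integer(names(tab)[tab < min_area_px])
  lab[lab %in% drop] <- 0L
  # relabel consecutively
  keep <- sort(unique(lab[lab > 0]))
  matrix(match(lab, keep, nomatch = 0L), nrow(image), ncol(image))
}

#' Disk-shaped nucleus mask
#'
#' Convenience constructor used with synthetic scenes.
#'
#' @param ny,nx frame size, pixels.
#' @param center `(y, x)` centre, 0-based pixels.
#' @param radius disk radius, pixels.
#' @return Logical matrix.
#' @export
disk_mask <- function(ny, nx, center, radius) {
  yy <- matrix(0:(ny - 1L), ny, nx)
  xx <- matrix(0:(nx - 1L), ny, nx, byrow = TRUE)
  (yy - center[1L])^2 + (xx - center[2L])^2 <= radius^2
}
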