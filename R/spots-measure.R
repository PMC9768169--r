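#' Disk-mean spot intensity and relative intensity
#'
#' Measures the mean intensity over all pixels whose centres lie within
#' `radius_px` of a (sub-pixel) spot centre, and — when a nuclear mean is
#' supplied — the relative intensity `disk_mean / nuclear_mean` used for
#' transcription-state calling.  Disks that extend past the image border
#' are measured over the available pixels and flagged.
#'
#' @param image 2D numeric matrix or [image_stack()].
#' @param center `(y, x)` spot centre, 0-based pixels.
#' @param radius_px disk radius, pixels (default 6).
#' @param nucleus_mean per-nucleus mean intensity (same channel); must be
#'   > 0 if given.
#' @return List: `disk_mean`, `relative_intensity` (`NA` without a nuclear
#'   mean), `n_pixels`, `partial` (disk clipped by the border?).
#' @export
measure_spot <- function(image, center, radius_px = 6, nucleus_mean = NULL) {
  if (inherits(image, "image_stack")) image <- stack_plane(image)
  stopifnot(is.matrix(image), length(center) == 2L)
  check_scalar(radius_px, "radius_px", lower = 0, strict_lower = TRUE)
  ny <- nrow(image); nx <- ncol(image)
  r0 <- center[1L]; c0 <- center[2L]
  ys <- max(0L, floor(r0 - radius_px)):min(ny - 1L, ceiling(r0 + radius_px))
  xs <- max(0L, floor(c0 - radius_px)):min(nx - 1L, ceiling(c0 + radius_px))
  yy <- rep(ys, length(xs)); xx <- rep(xs, each = length(ys))
  sel <- (yy - r0)^2 + (xx - c0)^2 <= radius_px^2
  partial <- r0 - radius_px < 0 || r0 + radius_px > ny - 1 ||
    c0 - radius_px < 0 || c0 + radius_px > nx - 1
  vals <- image[cbind(yy[sel] + 1L, xx[sel] + 1L)]
  disk_mean <- mean(vals)
  rel <- NA_real_
  if (!is.null(nucleus_mean)) {
    if (!is.finite(nucleus_mean) || nucleus_mean <= 0)
      stop_txspot("relative intensity undefined: nuclear mean <= 0")
    rel <- disk_mean / nucleus_mean
  }
  list(disk_mean = disk_mean, relative_intensity = rel,
       n_pixels = sum(sel), partial = partial)
}

#' Spot signal-to-noise ratio
#'
#' SNR of a DNA-label or transcription spot, defined as the spot mean
#' intensity divided by the standard deviation of the nuclear intensity
#' (`SNR = mu / sigma_N`), computed on a background-subtracted image.
#'
#' @param image 2D numeric matrix or [image_stack()].
#' @param center `(y, x)` spot centre, 0-based pixels.
#' @param nucleus_sd nuclear intensity SD (`sd` column of
#'   [measure_nuclei()]); must be > 0.
#' @param radius_px radius of the spot-mean disk (default 2 px,
#'   about a 0.5-um blob at 130 nm/px).
#' @return SNR (numeric scalar).
#' @export
compute_snr <- function(image, center, nucleus_sd, radius_px = 2) {
  check_scalar(nucleus_sd, "nucleus_sd", lower = 0)
  if (nucleus_sd == 0) stop_txspot("SNR undefined: nuclear SD is 0")
  mu <- measure_spot(image, center, radius_px = radius_px)$disk_mean
  mu / nucleus_sd
}

#' Count intensity foci by prominence
#'
#' Counts local maxima of topographic prominence >= `prominence` inside a
#' nucleus mask, via the grayscale h-dome transform (reconstruction by
#' dilation of `image - prominence` under `image`): a maximum survives iff
#' its dome reaches the full height `prominence`.  Matches the behaviour
#' of prominence-based "find maxima" tools.
#'
#' @param image 2D numeric matrix or [image_stack()].
#' @param mask logical matrix (nucleus); must contain at least one pixel.
#' @param prominence prominence threshold, > 0.
#' @return List: `count`, `mean_intensity` (mean over the focus peak
#'   intensities; `NA` when no foci), `peaks` (data frame `row`, `col`,
#'   `value`, 1-based).
#' @export
count_foci <- function(image, mask, prominence) {
  if (inherits(image, "image_stack")) image <- stack_plane(image)
  check_scalar(prominence, "prominence", lower = 0, strict_lower = TRUE)
  if (!is.matrix(mask) || !any(mask))
    stop_txspot("empty nucleus mask")
  img <- image
  img[!mask] <- min(image)   # suppress structure outside the mask
  # h-maxima transform: maxima of prominence < h merge into their
  # surroundings in the reconstruction and stop being regional maxima
  rec <- grayscale_reconstruct(img - prominence, img)
  nb_max <- neighbor_max(rec)
  cand <- rec >= nb_max & mask
  if (!any(cand))
    return(list(count = 0L, mean_intensity = NA_real_,
                peaks = data.frame(row = integer(), col = integer(),
                                   value = numeric())))
  lab <- EBImage::bwlabel(EBImage::Image(cand))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  nb_min <- neighbor_min(rec)
  peaks <- list()
  for (lb in sort(unique(lab[lab > 0]))) {
    sel <- which(lab == lb)
    # a true regional maximum has at least one strictly lower neighbour;
    # an all-flat region (e.g. a constant image) has none
    if (!any(nb_min[sel] < rec[sel] - 1e-12)) next
    best <- sel[which.max(image[sel])]
    k <- arrayInd(best, dim(image))
    peaks[[length(peaks) + 1L]] <- data.frame(row = k[1L], col = k[2L],
                                              value = image[best])
  }
  if (length(peaks) == 0)
    return(list(count = 0L, mean_intensity = NA_real_,
                peaks = data.frame(row = integer(), col = integer(),
                                   value = numeric())))
  peaks <- do.call(rbind, peaks)
  list(count = nrow(peaks), mean_intensity = mean(peaks$value),
       peaks = peaks)
}

# max / min over the 8-neighbourhood (excluding the centre)
neighbor_reduce <- function(m, fun, pad) {
  ny <- nrow(m); nx <- ncol(m)
  big <- matrix(pad, ny + 2L, nx + 2L)
  big[2:(ny + 1L), 2:(nx + 1L)] <- m
  out <- matrix(pad, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- fun(out, big[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx])
  }
  out
}
neighbor_max <- function(m) neighbor_reduce(m, pmax, -Inf)
neighbor_min <- function(m) neighbor_reduce(m, pmin, Inf)

# grayscale reconstruction by dilation of marker under mask image
grayscale_reconstruct <- function(marker, mask_img) {
  rec <- pmin(marker, mask_img)
  brush <- EBImage::makeBrush(3L, shape = "box")
  lo <- min(rec); hi <- max(mask_img)
  scale <- max(hi - lo, .Machine$double.eps)
  for (i in seq_len(10000L)) {
    dil <- EBImage::dilate(EBImage::Image((rec - lo) / scale), brush)
    nxt <- pmin(matrix(as.numeric(dil), nrow(rec), ncol(rec)) * scale + lo,
                mask_img)
    if (max(abs(nxt - rec)) < 1e-9 * scale) return(nxt)
    rec <- nxt
  }
  rec
}
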