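#' Calibrated image stack
#'
#' Container for pixel data with physical calibration.  `pixels` is a
#' numeric array whose axes are given by the `axes` string, a subset of
#' `"tzyx"` ending in `"yx"` (e.g. `"yx"`, `"tyx"`, `"zyx"`, `"tzyx"`).
#'
#' @param pixels numeric array (or matrix) of non-negative finite
#'   intensities.
#' @param axes axis string matching `dim(pixels)`.
#' @param pixel_size_nm physical pixel size, nm (default 130).
#' @param frame_interval_s time between frames, seconds (`NA` if not a
#'   time series).
#' @param channel optional channel label.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, axes = NULL, pixel_size_nm = 130,
                        frame_interval_s = NA_real_, channel = NA_character_) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = dim(pixels))
  if (!is.array(pixels) || !is.numeric(pixels))
    stop_txspot("'pixels' must be a numeric array")
  if (!all(is.finite(pixels)))
    stop_txspot("'pixels' must be finite")
  check_scalar(pixel_size_nm, "pixel_size_nm", lower = 0, strict_lower = TRUE)
  nd <- length(dim(pixels))
  if (is.null(axes))
    axes <- switch(as.character(nd), "2" = "yx", "3" = "tyx", "4" = "tzyx",
                   stop_txspot("cannot guess axes for %d-d array", nd))
  ax <- strsplit(axes, "")[[1L]]
  if (length(ax) != nd || !identical(tail(ax, 2L), c("y", "x")) ||
      anyDuplicated(ax) || !all(ax %in% c("t", "z", "y", "x")))
    stop_txspot("invalid axes '%s' for %d-d pixel array", axes, nd)
  structure(list(pixels = pixels, axes = axes,
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 channel = channel, provenance = list()),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack [%s] %s, %.0f nm/px", x$axes,
              paste(dim(x$pixels), collapse = " x "), x$pixel_size_nm))
  if (!is.na(x$frame_interval_s))
    cat(sprintf(", %.3g s/frame", x$frame_interval_s))
  if (!is.na(x$channel)) cat(sprintf(", channel %s", x$channel))
  cat("\n")
  if (length(x$provenance))
    cat("  steps:", paste(vapply(x$provenance, `[[`, "", "op"),
                          collapse = " -> "), "\n")
  invisible(x)
}

#' Extract one 2D plane from an image stack
#'
#' @param stack an [image_stack()].
#' @param t,z 1-based frame and slice indices (ignored when absent from the
#'   stack's axes).
#' @return A numeric matrix (y, x).
#' @export
stack_plane <- function(stack, t = 1L, z = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  ax <- strsplit(stack$axes, "")[[1L]]
  px <- stack$pixels
  idx <- rep(list(quote(expr = )), length(ax))
  names(idx) <- ax
  if ("t" %in% ax) idx[["t"]] <- t
  if ("z" %in% ax) idx[["z"]] <- z
  out <- do.call(`[`, c(list(px), unname(idx), list(drop = FALSE)))
  matrix(out, dim(px)[length(ax) - 1L], dim(px)[length(ax)])
}

n_frames <- function(stack) {
  ax <- strsplit(stack$axes, "")[[1L]]
  if ("t" %in% ax) dim(stack$pixels)[match("t", ax)] else 1L
}

n_slices <- function(stack) {
  ax <- strsplit(stack$axes, "")[[1L]]
  if ("z" %in% ax) dim(stack$pixels)[match("z", ax)] else 1L
}

#' Read / write TIFF image stacks
#'
#' Multi-page TIFF I/O for [image_stack()] objects.  Images are written as
#' 16-bit grayscale; intensities above 65535 are clipped with a warning.
#' Calibration metadata travels in a JSON sidecar written next to the TIFF
#' (same path with extension `.json`), and is restored on read when the
#' sidecar is present.
#'
#' @param stack an [image_stack()]; 2D or 3D (`tyx`/`zyx`).
#' @param path file path ending in `.tif` or `.tiff`.
#' @return `read_image_stack` returns an [image_stack()];
#'   `write_image_stack` returns `path` invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  ax <- strsplit(stack$axes, "")[[1L]]
  if (length(ax) > 3L)
    stop_txspot("TIFF writer supports 2D and 3D stacks (got axes '%s')",
                stack$axes)
  px <- stack$pixels
  if (any(px > 65535)) {
    warning("intensities clipped to 16-bit range")
    px <- pmin(px, 65535)
  }
  planes <- if (length(ax) == 2L) list(px / 65535) else
    lapply(seq_len(dim(px)[1L]), function(i)
      matrix(px[i, , ], dim(px)[2L], dim(px)[3L]) / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  meta <- list(axes = stack$axes, pixel_size_nm = stack$pixel_size_nm,
               frame_interval_s = stack$frame_interval_s,
               channel = stack$channel)
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  meta_path <- sub("\\.tiff?$", ".json", path)
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  axes <- meta$axes %||% if (length(planes) == 1L) "yx" else "tyx"
  d <- dim(planes[[1L]])
  px <- if (length(planes) == 1L) array(planes[[1L]], dim = d) else {
    arr <- array(0, dim = c(length(planes), d))
    for (i in seq_along(planes)) arr[i, , ] <- planes[[i]]
    arr
  }
  image_stack(px, axes = axes,
              pixel_size_nm = meta$pixel_size_nm %||% 130,
              frame_interval_s = meta$frame_interval_s %||% NA_real_,
              channel = meta$channel %||% NA_character_)
}
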