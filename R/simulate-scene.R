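#' Ground-truthed synthetic microscopy scene
#'
#' Describes a synthetic field of diffraction-limited fluorescent spots to
#' be rendered by [render_scene()].  Each spot is a 2D isotropic Gaussian
#' with a true sub-pixel centre (0-based pixel units), an amplitude and a
#' PSF sigma; the camera model is Poisson shot noise (optional) followed by
#' additive Gaussian read noise.
#'
#' @param ny,nx frame size in pixels.
#' @param spots data frame with columns `channel` (integer), `frame`
#'   (integer, 1-based), `y_px`, `x_px` (true centres, 0-based),
#'   `amplitude`, `sigma_px`.  All centres must lie inside the frame.
#' @param background constant background offset (camera counts).
#' @param shot_noise apply Poisson noise to the expected intensity?
#' @param read_sigma SD of additive Gaussian read noise.
#' @param pixel_size_nm physical pixel size, nm.
#' @param nucleus optional list `list(center = c(y, x), radius)` in pixels
#'   describing a disk-shaped nucleus (used by downstream mask helpers).
#' @return An object of class `ground_truth_scene`.
#' @export
ground_truth_scene <- function(ny, nx, spots, background = 0,
                               shot_noise = FALSE, read_sigma = 0,
                               pixel_size_nm = 130, nucleus = NULL) {
  stopifnot(ny >= 1, nx >= 1)
  check_scalar(background, "background", lower = 0)
  check_scalar(read_sigma, "read_sigma", lower = 0)
  check_scalar(pixel_size_nm, "pixel_size_nm", lower = 0, strict_lower = TRUE)
  need <- c("channel", "frame", "y_px", "x_px", "amplitude", "sigma_px")
  if (!is.data.frame(spots)) stop_txspot("'spots' must be a data frame")
  if (nrow(spots) > 0) {
    miss <- setdiff(need, names(spots))
    if (length(miss)) stop_txspot("spots missing column(s): %s",
                                  paste(miss, collapse = ", "))
    if (any(spots$sigma_px <= 0)) stop_txspot("sigma_px must be > 0")
    if (any(spots$y_px < 0 | spots$y_px > ny - 1 |
            spots$x_px < 0 | spots$x_px > nx - 1))
      stop_txspot("all spot centres must lie inside the frame")
  } else {
    spots <- data.frame(channel = integer(), frame = integer(),
                        y_px = numeric(), x_px = numeric(),
                        amplitude = numeric(), sigma_px = numeric())
  }
  structure(list(ny = as.integer(ny), nx = as.integer(nx), spots = spots,
                 background = background, shot_noise = shot_noise,
                 read_sigma = read_sigma, pixel_size_nm = pixel_size_nm,
                 nucleus = nucleus),
            class = "ground_truth_scene")
}

# expected (noise-free) image of one channel/frame
scene_expected_image <- function(scene, channel = 1L, frame = 1L) {
  img <- matrix(scene$background, scene$ny, scene$nx)
  sp <- scene$spots[scene$spots$channel == channel &
                      scene$spots$frame == frame, , drop = FALSE]
  if (nrow(sp) == 0) return(img)
  yy <- 0:(scene$ny - 1L); xx <- 0:(scene$nx - 1L)
  for (i in seq_len(nrow(sp))) {
    gy <- exp(-(yy - sp$y_px[i])^2 / (2 * sp$sigma_px[i]^2))
    gx <- exp(-(xx - sp$x_px[i])^2 / (2 * sp$sigma_px[i]^2))
    img <- img + sp$amplitude[i] * outer(gy, gx)
  }
  img
}

#' Render a synthetic scene to an image stack
#'
#' Evaluates each spot's Gaussian profile at pixel centres, adds the
#' background, and applies the camera noise model (Poisson shot noise on
#' the expected intensity, then additive Gaussian read noise, both
#' optional).  Negative values after read noise are clipped at 0.
#'
#' @param scene a [ground_truth_scene()].
#' @param channel channel to render.
#' @param seed optional integer seed for the noise draws.
#' @return An [image_stack()] (`yx` for a single frame, `tyx` otherwise);
#'   the scene itself (ground truth) is attached as attribute `scene`.
#' @export
render_scene <- function(scene, channel = 1L, seed = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (!is.null(seed)) set.seed(seed)
  frames <- sort(unique(c(1L, scene$spots$frame)))
  nt <- max(frames)
  arr <- array(0, dim = c(nt, scene$ny, scene$nx))
  for (f in seq_len(nt)) {
    img <- scene_expected_image(scene, channel, f)
    if (scene$shot_noise)
      img <- matrix(rpois(length(img), img), scene$ny, scene$nx)
    if (scene$read_sigma > 0)
      img <- img + matrix(rnorm(length(img), sd = scene$read_sigma),
                          scene$ny, scene$nx)
    arr[f, , ] <- pmax(img, 0)
  }
  st <- if (nt == 1L)
    image_stack(matrix(arr[1L, , ], scene$ny, scene$nx), axes = "yx",
                pixel_size_nm = scene$pixel_size_nm)
  else
    image_stack(arr, axes = "tyx", pixel_size_nm = scene$pixel_size_nm)
  attr(st, "scene") <- scene
  st
}

#' Simulate a two-channel anchor/cluster scene
#'
#' Builds a synthetic single-frame field emulating regulatory-factor
#' cluster imaging around a tagged gene locus: channel 1 holds one anchor
#' spot (the DNA label), channel 2 holds `n_clusters` factor clusters.  The
#' designated nearest cluster is placed at a distance drawn from a
#' log-normal distribution whose median is `distance_median_nm` (so the
#' configured median is exact in distribution); decoy clusters are placed
#' strictly farther from the anchor.  The ground-truth nearest distance is
#' recorded.
#'
#' @param state `"ON"` or `"OFF"`; stored with the truth record (the
#'   spatial statistics are fully determined by `distance_median_nm`).
#' @param distance_median_nm median anchor-to-nearest-cluster distance, nm.
#' @param n_clusters total clusters in channel 2 (>= 1).
#' @param dispersion log-scale SD of the nearest-distance distribution.
#' @param ny,nx frame size, pixels.
#' @param psf_sigma_px PSF sigma of all spots, pixels.
#' @param amplitude peak amplitude of rendered spots (counts above
#'   background).
#' @param background,shot_noise,read_sigma camera model, as in
#'   [ground_truth_scene()].
#' @param pixel_size_nm physical pixel size, nm.
#' @param seed optional integer seed.
#' @return List with elements `scene` (a [ground_truth_scene()]) and
#'   `truth` (list: `state`, `anchor_px`, `clusters_px`,
#'   `nearest_distance_nm`).
#' @export
simulate_cluster_scene <- function(state = c("ON", "OFF"),
                                   distance_median_nm, n_clusters = 3L,
                                   dispersion = 0.5, ny = 41L, nx = 41L,
                                   psf_sigma_px = 1.3, amplitude = 400,
                                   background = 100, shot_noise = TRUE,
                                   read_sigma = 5, pixel_size_nm = 130,
                                   seed = NULL) {
  state <- match.arg(state)
  check_scalar(distance_median_nm, "distance_median_nm", lower = 0)
  check_scalar(dispersion, "dispersion", lower = 0)
  stopifnot(n_clusters >= 1)
  if (!is.null(seed)) set.seed(seed)

  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  anchor <- c(cy, cx) + runif(2L, -1, 1)
  margin <- 5  # keep spots clear of the border so refinement windows fit
  inside <- function(p) all(p >= margin) && p[1L] <= ny - 1 - margin &&
    p[2L] <= nx - 1 - margin

  # nearest cluster: log-normal radial distance, uniform angle
  repeat {
    d_nm <- if (dispersion > 0)
      rlnorm(1L, meanlog = log(max(distance_median_nm, 1e-12)),
             sdlog = dispersion)
    else distance_median_nm
    theta <- runif(1L, 0, 2 * pi)
    nearest <- anchor + d_nm / pixel_size_nm * c(sin(theta), cos(theta))
    if (inside(nearest)) break
  }

  clusters <- matrix(nearest, 1L, 2L)
  n_try <- 0L
  while (nrow(clusters) < n_clusters && n_try < 10000L) {
    n_try <- n_try + 1L
    dd_nm <- d_nm * runif(1L, 1.4, 3) + 400
    theta <- runif(1L, 0, 2 * pi)
    p <- anchor + dd_nm / pixel_size_nm * c(sin(theta), cos(theta))
    sep_ok <- all(sqrt(rowSums(sweep(clusters, 2L, p)^2)) >= 6.5)
    if (inside(p) && sep_ok) clusters <- rbind(clusters, p)
  }

  spots <- data.frame(
    channel = c(1L, rep(2L, nrow(clusters))),
    frame = 1L,
    y_px = c(anchor[1L], clusters[, 1L]),
    x_px = c(anchor[2L], clusters[, 2L]),
    amplitude = amplitude * runif(nrow(clusters) + 1L, 0.8, 1.2),
    sigma_px = psf_sigma_px)
  scene <- ground_truth_scene(ny, nx, spots, background = background,
                              shot_noise = shot_noise,
                              read_sigma = read_sigma,
                              pixel_size_nm = pixel_size_nm)
  d_all <- sqrt(rowSums(sweep(clusters, 2L, anchor)^2)) * pixel_size_nm
  list(scene = scene,
       truth = list(state = state, anchor_px = anchor,
                    clusters_px = clusters,
                    nearest_distance_nm = min(d_all)))
}
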