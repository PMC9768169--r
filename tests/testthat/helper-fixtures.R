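# shared synthetic fixtures built in code

# noise-free image with 2D Gaussian spots; centers 0-based (y, x)
render_gaussians <- function(ny, nx, centers, amplitude = 100,
                             sigma = 1.5, background = 0) {
  sp <- data.frame(channel = 1L, frame = 1L,
                   y_px = centers[, 1L], x_px = centers[, 2L],
                   amplitude = amplitude, sigma_px = sigma)
  sc <- ground_truth_scene(ny, nx, sp, background = background)
  stack_plane(render_scene(sc))
}

# brute-force disk mean: loop over every pixel
disk_mean_oracle <- function(img, center, radius) {
  acc <- c(); n <- 0
  for (r in 0:(nrow(img) - 1L)) for (cc in 0:(ncol(img) - 1L)) {
    if ((r - center[1L])^2 + (cc - center[2L])^2 <= radius^2) {
      acc <- c(acc, img[r + 1L, cc + 1L]); n <- n + 1
    }
  }
  mean(acc)
}

# brute-force MSCD: explicit double loop over time pairs
mscd_oracle <- function(d, lag) {
  vals <- c()
  for (t in seq_len(length(d) - lag))
    vals <- c(vals, (d[t] - d[t + lag])^2)
  mean(vals)
}

# brute-force time-averaged MSD (um^2) for one track in nm
msd_oracle <- function(pos_nm, lag) {
  p <- pos_nm / 1000
  vals <- c()
  for (t in seq_len(nrow(p) - lag))
    vals <- c(vals, sum((p[t + lag, ] - p[t, ])^2))
  mean(vals)
}
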