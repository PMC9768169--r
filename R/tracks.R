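#' Link per-frame spots into trajectories
#'
#' Greedy nearest-neighbour linking: within each frame, all (track, spot)
#' pairs closer than `search_range_px` are assigned in order of increasing
#' displacement; ties are broken by the smaller displacement first, then by
#' the lower candidate order (spots ordered by `(y, x)` within the frame,
#' so linking does not depend on input row order).  A track may skip up to
#' `memory_frames` consecutive frames; unmatched spots seed new tracks.
#' Tracks whose longest run of consecutive frames is <= `min_consecutive`
#' are discarded (a track must be detected in more than `min_consecutive`
#' consecutive frames to be kept).
#'
#' @param spots data frame with columns `frame` (integer), `y_px`, `x_px`;
#'   extra columns are carried through.
#' @param search_range_px maximum frame-to-frame displacement (default 2).
#' @param memory_frames maximum tolerated gap, frames (default 4).
#' @param min_consecutive consecutive-detection filter (default 50).
#' @return Data frame: input columns plus `track` (integer id); attribute
#'   `all_tracks` holds the unfiltered linking.
#' @export
link_tracks <- function(spots, search_range_px = 2, memory_frames = 4,
                        min_consecutive = 50) {
  stopifnot(is.data.frame(spots),
            all(c("frame", "y_px", "x_px") %in% names(spots)))
  spots <- spots[order(spots$frame, spots$y_px, spots$x_px), , drop = FALSE]
  rownames(spots) <- NULL
  spots$track <- NA_integer_
  last_pos <- list()    # per track: c(y, x)
  last_frame <- integer(0)
  n_tracks <- 0L
  for (f in sort(unique(spots$frame))) {
    idx <- which(spots$frame == f)
    active <- which(last_frame >= f - memory_frames - 1L)
    if (length(active) && length(idx)) {
      # candidate pairs within range
      pairs <- expand.grid(spot = idx, track = active)
      py <- spots$y_px[pairs$spot]; px <- spots$x_px[pairs$spot]
      ty <- vapply(pairs$track, function(k) last_pos[[k]][1L], 0)
      tx <- vapply(pairs$track, function(k) last_pos[[k]][2L], 0)
      pairs$dist <- sqrt((py - ty)^2 + (px - tx)^2)
      pairs <- pairs[pairs$dist <= search_range_px, , drop = FALSE]
      pairs <- pairs[order(pairs$dist, match(pairs$spot, idx), pairs$track), ,
                     drop = FALSE]
      used_spot <- integer(0); used_track <- integer(0)
      for (i in seq_len(nrow(pairs))) {
        s <- pairs$spot[i]; k <- pairs$track[i]
        if (s %in% used_spot || k %in% used_track) next
        spots$track[s] <- k
        last_pos[[k]] <- c(spots$y_px[s], spots$x_px[s])
        last_frame[k] <- f
        used_spot <- c(used_spot, s); used_track <- c(used_track, k)
      }
    }
    for (s in idx[is.na(spots$track[idx])]) {
      n_tracks <- n_tracks + 1L
      spots$track[s] <- n_tracks
      last_pos[[n_tracks]] <- c(spots$y_px[s], spots$x_px[s])
      last_frame[n_tracks] <- f
    }
  }
  all_tracks <- spots
  keep <- vapply(split(spots$frame, spots$track), function(fr)
    max(tabulate_consecutive(sort(fr))), 0L)
  keep_ids <- as.integer(names(keep)[keep > min_consecutive])
  out <- spots[spots$track %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_tracks") <- all_tracks
  out
}

# lengths of maximal runs of consecutive integers
tabulate_consecutive <- function(fr) {
  if (length(fr) == 0) return(0L)
  r <- rle(cumsum(c(TRUE, diff(fr) != 1L)))
  r$lengths
}
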