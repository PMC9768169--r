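#' Two-state (telegraph) promoter parameters
#'
#' Bundles the kinetic parameters of a two-state promoter: a gene switches
#' between a transcriptionally active ON state and a quiescent OFF state
#' with first-order rates, and initiates transcripts as a Poisson process
#' while ON.
#'
#' @param k_on switching rate OFF -> ON, per minute.
#' @param k_off switching rate ON -> OFF, per minute.
#' @param k_init initiation rate while ON, transcripts per minute.
#' @param duration total simulated time, minutes.
#' @param dt sampling interval of the discretized state trace, minutes.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return An object of class `telegraph_params`.
#' @export
telegraph_params <- function(k_on, k_off, k_init, duration, dt, seed = NULL) {
  check_scalar(k_on, "k_on", lower = 0)
  check_scalar(k_off, "k_off", lower = 0)
  check_scalar(k_init, "k_init", lower = 0)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = dt)
  structure(list(k_on = k_on, k_off = k_off, k_init = k_init,
                 duration = duration, dt = dt, seed = seed),
            class = "telegraph_params")
}

#' Simulate a telegraph-model promoter state trace
#'
#' Exact (Gillespie) simulation of the two-state promoter: ON/OFF dwell
#' times are drawn from their exponential distributions and the continuous
#' state path is then discretized onto the sampling grid, so the discrete
#' trace carries no time-step bias.  Initiation events are drawn as a
#' Poisson process restricted to ON intervals.
#'
#' @param params a [telegraph_params()] object.
#' @param start_state `"stationary"` (draw the initial state from the
#'   stationary distribution), `"on"` or `"off"`.
#' @return An object of class `telegraph_trace`: list with `times` (grid,
#'   min), `state` (integer 0/1 per grid point), `events` (initiation times,
#'   min), `on_intervals` (2-column matrix of ON interval start/end) and
#'   `params`.
#' @examples
#' tr <- simulate_telegraph(telegraph_params(1, 1, 5, 100, 0.5, seed = 1))
#' mean(tr$state)  # close to k_on / (k_on + k_off) = 0.5
#' @export
simulate_telegraph <- function(params, start_state = "stationary") {
  stopifnot(inherits(params, "telegraph_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  k_on <- params$k_on; k_off <- params$k_off
  duration <- params$duration

  p_on <- if (k_on + k_off > 0) k_on / (k_on + k_off) else 0.5
  state <- switch(match.arg(start_state, c("stationary", "on", "off")),
                  stationary = as.integer(runif(1) < p_on),
                  on = 1L, off = 0L)

  # Gillespie: alternate exponential dwell times until the horizon.
  t_now <- 0
  breaks <- numeric(0)   # switch times
  states <- integer(0)   # state on [break[i-1], break[i])
  s <- state
  while (t_now < duration) {
    rate <- if (s == 1L) k_off else k_on
    dwell <- if (rate > 0) rexp(1L, rate) else Inf
    t_next <- min(t_now + dwell, duration)
    breaks <- c(breaks, t_next)
    states <- c(states, s)
    t_now <- t_next
    s <- 1L - s
  }

  # ON intervals and Poisson initiation events within them.
  starts <- c(0, head(breaks, -1L))
  on_idx <- which(states == 1L)
  on_intervals <- cbind(start = starts[on_idx], end = breaks[on_idx])
  events <- numeric(0)
  if (params$k_init > 0 && nrow(on_intervals) > 0) {
    for (i in seq_len(nrow(on_intervals))) {
      len <- on_intervals[i, 2L] - on_intervals[i, 1L]
      n <- rpois(1L, params$k_init * len)
      if (n > 0)
        events <- c(events, sort(runif(n, on_intervals[i, 1L],
                                       on_intervals[i, 2L])))
    }
  }

  times <- seq(0, duration, by = params$dt)
  # state at grid time = state of the interval [start, break) containing it
  grid_state <- states[pmin(findInterval(times, breaks) + 1L, length(states))]

  structure(list(times = times, state = as.integer(grid_state),
                 events = events, on_intervals = on_intervals,
                 params = params),
            class = "telegraph_trace")
}

#' @export
print.telegraph_trace <- function(x, ...) {
  cat("Telegraph promoter trace\n")
  cat(sprintf("  duration %.1f min, dt %.3g min, %d initiation events\n",
              x$params$duration, x$params$dt, length(x$events)))
  cat(sprintf("  ON occupancy %.3f (stationary expectation %.3f)\n",
              mean(x$state),
              x$params$k_on / max(x$params$k_on + x$params$k_off, .Machine$double.eps)))
  invisible(x)
}

#' Simulate a dual (TSS-proximal / 3'UTR) nascent reporter pair
#'
#' Converts a set of transcription initiation times into intensity traces
#' of two stem-loop reporters read by distinct coat proteins: one cassette
#' inserted near the transcription start site (MCP channel) and one in the
#' 3'UTR (PCP channel), `separation_kb` apart along the gene.  Each
#' initiated polymerase lights up the TSS-proximal reporter essentially at
#' its initiation time and reaches the 3'UTR reporter after the elongation
#' delay `separation_kb / elongation_rate_kb_per_min`.  Each reporter's
#' signal then persists for an exponentially distributed residence time
#' (mean `dwell_min`): the TSS-proximal repeat sits in an intron that is
#' spliced out and degraded, while the 3'UTR repeat stays on the transcript
#' until release, so both tags have their own finite residence rather than
#' remaining until the polymerase terminates.  The same residence draw is
#' used for both tags of a transcript, making the PCP trace a pure
#' time-shifted copy of the MCP trace and placing the population
#' cross-correlation peak at the elongation delay.
#'
#' @param events numeric vector of initiation times (min).
#' @param separation_kb genomic distance between the two reporter cassettes
#'   (kb), >= 0.
#' @param elongation_rate_kb_per_min polymerase elongation rate (kb/min), > 0.
#' @param dwell_min mean residence time of a tagged transcript's signal
#'   (min); 0 gives one-sample pulses.
#' @param dt sampling interval (min).
#' @param duration trace length (min); default covers the last event plus
#'   the delay and five dwell times.
#' @param seed optional integer seed for the residence-time draws.
#' @return Object of class `reporter_pair`: list with `times`, `mcp`,
#'   `pcp` (unit-transcript intensities) and `true_delay` (min).
#' @export
simulate_reporter_pair <- function(events, separation_kb,
                                   elongation_rate_kb_per_min,
                                   dwell_min = 3, dt = 1,
                                   duration = NULL, seed = NULL) {
  check_scalar(separation_kb, "separation_kb", lower = 0)
  check_scalar(elongation_rate_kb_per_min, "elongation_rate_kb_per_min",
               lower = 0, strict_lower = TRUE)
  check_scalar(dwell_min, "dwell_min", lower = 0)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) set.seed(seed)
  events <- as.numeric(events)
  delay <- separation_kb / elongation_rate_kb_per_min
  if (is.null(duration))
    duration <- if (length(events)) max(events) + delay + 5 * dwell_min else delay + 5 * dwell_min
  times <- seq(0, duration, by = dt)

  dwell <- if (dwell_min > 0 && length(events))
    rexp(length(events), 1 / dwell_min) else rep(0, length(events))

  box_sum <- function(onsets, offsets) {
    sig <- numeric(length(times))
    for (i in seq_along(onsets)) {
      on <- times >= onsets[i] & times <= offsets[i]
      sig[on] <- sig[on] + 1
    }
    sig
  }
  # zero-dwell events still occupy the sample they start in
  mcp <- box_sum(events, events + pmax(dwell, dt / 2))
  pcp <- box_sum(events + delay, events + delay + pmax(dwell, dt / 2))

  structure(list(times = times, mcp = mcp, pcp = pcp, true_delay = delay),
            class = "reporter_pair")
}

#' @export
print.reporter_pair <- function(x, ...) {
  cat(sprintf("Reporter pair trace: %d samples, true delay %.3g min\n",
              length(x$times), x$true_delay))
  invisible(x)
}
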