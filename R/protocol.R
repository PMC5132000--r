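#' Stimulation protocol
#'
#' Describes a pulse-train depolarization protocol: a set of brief
#' high-K+ pulses applied during an observation window. The protocol
#' defines the piecewise time axis of the hazard models: time is
#' partitioned into the first pulse, later pulses, and the rest
#' intervals between/around pulses. Time zero is the onset of the
#' first pulse and all times are in seconds.
#'
#' @param pulse_starts Strictly increasing numeric vector of pulse onset
#'   times (s). Default: ten pulses at 0, 10, ..., 90 s.
#' @param pulse_duration Duration of each pulse (s). Default 1.
#' @param observation_end End of the observation window (s); all granules
#'   still unreleased at this time are administratively censored.
#'   Default 100.
#' @return An object of class `stim_protocol`.
#' @examples
#' p <- stim_protocol()
#' segment_of(c(0.5, 10, 11, 5), p)
#' @export
stim_protocol <- function(pulse_starts = seq(0, 90, by = 10),
                          pulse_duration = 1,
                          observation_end = 100) {
  stopifnot(is.numeric(pulse_starts), length(pulse_starts) >= 1,
            is.numeric(pulse_duration), length(pulse_duration) == 1,
            pulse_duration > 0,
            is.numeric(observation_end), length(observation_end) == 1)
  if (is.unsorted(pulse_starts, strictly = TRUE))
    stop("`pulse_starts` must be strictly increasing")
  if (any(pulse_starts < 0) ||
      any(pulse_starts + pulse_duration > observation_end))
    stop("every pulse interval must lie within [0, observation_end]")
  if (any(diff(pulse_starts) < pulse_duration))
    stop("pulse intervals must be disjoint")
  structure(
    list(pulse_starts = as.numeric(pulse_starts),
         pulse_duration = as.numeric(pulse_duration),
         observation_end = as.numeric(observation_end)),
    class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("Stimulation protocol:", length(x$pulse_starts), "pulses of",
      x$pulse_duration, "s at t =", paste(utils::head(x$pulse_starts, 4),
                                          collapse = ", "),
      if (length(x$pulse_starts) > 4) "...", "\n")
  cat("Observation window: [0,", x$observation_end, ") s;",
      "administrative censoring at", x$observation_end, "s\n")
  invisible(x)
}

segment_levels <- c("first_pulse", "later_pulse", "between")

#' Segment classification of time points
#'
#' Classifies each time into one of the three hazard segments: the first
#' pulse (`first_pulse`), any later pulse (`later_pulse`), or outside
#' pulses (`between`). Pulse intervals are half-open, `[s, s + duration)`,
#' so a time exactly at the end of a pulse is `between`.
#'
#' @param t Numeric vector of times in `[0, observation_end)`.
#' @param protocol A [stim_protocol()].
#' @return Factor with levels `first_pulse`, `later_pulse`, `between`.
#' @export
segment_of <- function(t, protocol = stim_protocol()) {
  stopifnot(inherits(protocol, "stim_protocol"), is.numeric(t))
  if (any(t < 0 | t >= protocol$observation_end))
    stop("times must lie in [0, observation_end)")
  # index of the pulse interval containing t, 0 if none
  idx <- findInterval(t, protocol$pulse_starts)
  in_pulse <- idx >= 1 &
    t < protocol$pulse_starts[pmax(idx, 1)] + protocol$pulse_duration
  cls <- ifelse(in_pulse, ifelse(idx == 1, 1L, 2L), 3L)
  factor(segment_levels[cls], levels = segment_levels)
}

#' Segment table of a protocol
#'
#' Internal partition of `[0, observation_end)` into maximal half-open
#' intervals of constant segment class, in time order.
#'
#' @param protocol A [stim_protocol()].
#' @return Data frame with columns `start`, `end`, `segment`.
#' @export
segment_breaks <- function(protocol = stim_protocol()) {
  ps <- protocol$pulse_starts
  dur <- protocol$pulse_duration
  end <- protocol$observation_end
  cuts <- sort(unique(c(0, ps, ps + dur, end)))
  cuts <- cuts[cuts <= end]
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1]
  mid <- (lo + hi) / 2
  data.frame(start = lo, end = hi, segment = segment_of(mid, protocol))
}
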