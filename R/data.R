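#' Clustered single-granule event dataset
#'
#' Bundles a table of granule-level right-censored event times with the
#' stimulation protocol that defines the time axis. One row per granule:
#' the cell it belongs to (the statistical cluster), the observed time
#' (time of exocytosis, or the censoring time), the event indicator and
#' the cell-level binary covariate.
#'
#' @param data Data frame with columns `cell_id`, `granule_id`, `time`
#'   (s), `event` (1 = exocytosis observed, 0 = censored) and `diabetic`
#'   (0 = healthy donor, 1 = diabetic donor).
#' @param protocol A [stim_protocol()].
#' @return Object of class `granule_data`: a list with elements `data`
#'   and `protocol`.
#' @details Censoring is administrative: observation stops for all
#'   granules at `observation_end`, so a censored row must carry
#'   `time == observation_end` (a deviation raises a validation
#'   warning). Events recorded exactly at `observation_end` are accepted
#'   as observed. The covariate must be constant within a cell.
#' @export
granule_data <- function(data, protocol = stim_protocol()) {
  req <- c("cell_id", "granule_id", "time", "event", "diabetic")
  if (!all(req %in% names(data)))
    stop("event table must have columns: ", paste(req, collapse = ", "))
  data <- as.data.frame(data)[req]
  stopifnot(is.numeric(data$time), all(data$event %in% c(0, 1)),
            all(data$diabetic %in% c(0, 1)))
  if (any(data$time <= 0) || any(data$time > protocol$observation_end))
    stop("times must lie in (0, observation_end]")
  bad_cells <- tapply(data$diabetic, data$cell_id,
                      function(x) length(unique(x)) > 1)
  if (any(bad_cells))
    stop("covariate `diabetic` varies within cell(s): ",
         paste(names(bad_cells)[bad_cells], collapse = ", "))
  off <- data$event == 0 & data$time != protocol$observation_end
  if (any(off))
    warning(sum(off), " censored row(s) have time != observation_end; ",
            "administrative censoring expects censoring at experiment end")
  data$event <- as.integer(data$event)
  data$diabetic <- as.integer(data$diabetic)
  structure(list(data = data, protocol = protocol), class = "granule_data")
}

#' @export
print.granule_data <- function(x, ...) {
  d <- x$data
  cat("Granule event dataset:", nrow(d), "granules in",
      length(unique(d$cell_id)), "cells (clusters)\n")
  cat("  events:", sum(d$event), " censored:", sum(d$event == 0), "\n")
  tb <- table(tapply(d$diabetic, d$cell_id, function(v) v[1]))
  cat("  cells by covariate: healthy =", sum(tb[names(tb) == "0"]),
      ", diabetic =", sum(tb[names(tb) == "1"]), "\n")
  invisible(x)
}

n_clusters <- function(gd) length(unique(gd$data$cell_id))

#' Read / write the granule event table
#'
#' The on-disk format is a plain comma-separated file with header
#' `cell_id,granule_id,time,event,diabetic`. The protocol is not
#' inferred from the data; it is supplied separately (see
#' [read_protocol()]).
#'
#' @param file Path of the CSV file.
#' @param protocol A [stim_protocol()] to attach on reading.
#' @return `read_events()` returns a [granule_data()];
#'   `write_events()` returns `file` invisibly.
#' @export
read_events <- function(file, protocol = stim_protocol()) {
  granule_data(utils::read.csv(file), protocol)
}

#' @rdname read_events
#' @param gd A [granule_data()] object to write.
#' @export
write_events <- function(gd, file) {
  stopifnot(inherits(gd, "granule_data"))
  utils::write.csv(gd$data, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write a stimulation-protocol config
#'
#' YAML file with keys `pulse_starts`, `pulse_duration`,
#' `observation_end`.
#'
#' @param file Path of the config file.
#' @return `read_protocol()` returns a [stim_protocol()].
#' @export
read_protocol <- function(file) {
  cfg <- yaml::read_yaml(file)
  stim_protocol(pulse_starts = cfg$pulse_starts,
                pulse_duration = cfg$pulse_duration,
                observation_end = cfg$observation_end)
}

#' @rdname read_protocol
#' @param protocol A [stim_protocol()] to write.
#' @export
write_protocol <- function(protocol, file) {
  stopifnot(inherits(protocol, "stim_protocol"))
  yaml::write_yaml(unclass(protocol), file)
  invisible(file)
}

#' Export survival/incidence curves as a tidy table
#'
#' @param curves Named list of [survival_curve()] objects (as returned
#'   by [incidence_components()]).
#' @param X Covariate value the curves condition on.
#' @return Data frame with columns `time`, `value`, `component`,
#'   `covariate`.
#' @export
curves_to_table <- function(curves, X = 0) {
  do.call(rbind, lapply(names(curves), function(nm) {
    data.frame(time = curves[[nm]]$time, value = curves[[nm]]$value,
               component = nm, covariate = X)
  }))
}
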