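#' Simulation design for clustered granule-release data
#'
#' Describes a synthetic experiment with the statistical structure of a
#' pulsed-depolarization TIRF recording: cells (clusters) from healthy
#' and diabetic donors, a fixed number of docked granules followed per
#' cell, a two-point IRP frailty on each granule, and an optional
#' cell-level multiplicative heterogeneity factor that induces
#' within-cell correlation (unmodeled by the fitted likelihood, as in
#' real data, where it is handled by cluster-robust inference).
#'
#' @param n_cells_healthy,n_cells_diabetic Cell counts per group.
#'   Defaults 11 and 8, the study's cluster structure (J = 19).
#' @param granules_per_cell Number of docked granules followed per cell
#'   (scalar, recycled, or a vector of length `n_cells_healthy +
#'   n_cells_diabetic`). Default 100.
#' @param truth A [frailty_params()] used as the generating mechanism.
#'   Default: pulse rate 0.00117 s^-1, between-pulse rate 0.00014 s^-1,
#'   diabetes effect 1.43 between pulses, frailty ratio 499.5 and IRP
#'   probabilities 0.026 (healthy) / 0.010 (diabetic).
#' @param cell_heterogeneity_variance Variance v >= 0 of the mean-one
#'   gamma cell factor w; v = 0 gives conditionally independent granules
#'   within a cell. Default 0.5.
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(n_cells_healthy = 11,
                              n_cells_diabetic = 8,
                              granules_per_cell = 100,
                              truth = frailty_params(
                                alpha1 = log(0.00117),
                                alpha2 = log(0.00014),
                                beta2 = 1.43, eta = 499.5,
                                pi0 = 0.026, pi1 = 0.010),
                              cell_heterogeneity_variance = 0.5) {
  stopifnot(n_cells_healthy >= 0, n_cells_diabetic >= 0,
            n_cells_healthy + n_cells_diabetic >= 1,
            inherits(truth, "frailty_params"),
            cell_heterogeneity_variance >= 0,
            all(granules_per_cell >= 1))
  n_cells <- n_cells_healthy + n_cells_diabetic
  gpc <- rep_len(as.integer(granules_per_cell), n_cells)
  structure(list(n_cells_healthy = as.integer(n_cells_healthy),
                 n_cells_diabetic = as.integer(n_cells_diabetic),
                 granules_per_cell = gpc, truth = truth,
                 cell_heterogeneity_variance = cell_heterogeneity_variance),
            class = "simulation_design")
}

#' Draw two-point frailties
#'
#' Each granule independently belongs to the IRP with probability
#' `pi_x`, in which case its frailty is `eta`; otherwise 1. Uses the
#' current R random-number stream.
#'
#' @param n Number of granules.
#' @param pi_x IRP probability in `[0, 1]`.
#' @param eta Frailty ratio (>= 1 expected).
#' @return Numeric vector of length `n` with values in `{1, eta}`.
#' @export
assign_frailties <- function(n, pi_x, eta) {
  if (pi_x < 0 || pi_x > 1) stop("`pi_x` must be a probability in [0, 1]")
  stopifnot(eta > 0, n >= 0)
  ifelse(stats::runif(n) < pi_x, eta, 1)
}

#' Invert the cumulative hazard (inverse-transform sampling)
#'
#' Solves `multiplier * M0(t | X) = -log(u)` for `t`, segment by
#' segment: within a protocol segment the cumulative hazard is linear,
#' so the inversion is exact. When the total hazard accumulated by
#' `observation_end` is smaller than `-log(u)` the granule is censored.
#'
#' @param u Uniform(0,1) deviates (vectorized).
#' @param multiplier Positive hazard multiplier(s) `z * w` (frailty
#'   times cell factor), recycled against `u`.
#' @param params A [frailty_params()].
#' @param X Covariate value (scalar).
#' @param protocol A [stim_protocol()].
#' @return Data frame with columns `time` and `event` (0 = censored at
#'   `observation_end`).
#' @export
invert_cumulative_hazard <- function(u, multiplier, params, X = 0,
                                     protocol = stim_protocol()) {
  stopifnot(all(u > 0), all(u < 1), all(multiplier > 0))
  n <- length(u)
  mult <- rep_len(multiplier, n)
  target <- -log(u) / mult              # required baseline cumulative hazard
  sb <- segment_breaks(protocol)
  rates <- segment_rates(params, X, sb$segment)
  cum_hi <- cumsum(rates * (sb$end - sb$start))  # M0 at segment right ends
  cum_lo <- c(0, cum_hi[-length(cum_hi)])
  total <- cum_hi[length(cum_hi)]
  time <- rep(protocol$observation_end, n)
  event <- as.integer(target <= total)
  hit <- which(event == 1)
  if (length(hit)) {
    # first segment whose cumulative right end reaches the target
    seg <- findInterval(target[hit], cum_hi, left.open = TRUE) + 1L
    seg <- pmin(seg, nrow(sb))
    time[hit] <- sb$start[seg] + (target[hit] - cum_lo[seg]) / rates[seg]
  }
  data.frame(time = time, event = event)
}

#' Simulate a clustered granule event dataset
#'
#' Generates a [granule_data()] under the discrete-frailty model with
#' optional shared cell-level heterogeneity. Per cell, in a fixed order
#' (healthy cells first, then diabetic): one gamma cell factor `w`
#' (mean 1, variance v; `w = 1` exactly when v = 0), then the granule
#' frailties via [assign_frailties()], then the granule uniforms for
#' inverse-transform sampling. This fixed consumption order makes seeds
#' portable across runs.
#'
#' @param design A [simulation_design()].
#' @param protocol A [stim_protocol()].
#' @param seed Optional integer seed (set locally).
#' @return A [granule_data()]; the generating design is attached as
#'   attribute `"design"`.
#' @export
simulate_dataset <- function(design = simulation_design(),
                             protocol = stim_protocol(), seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(seed)) set.seed(seed)
  v <- design$cell_heterogeneity_variance
  tr <- design$truth
  n_cells <- design$n_cells_healthy + design$n_cells_diabetic
  Xcell <- rep(c(0L, 1L),
               c(design$n_cells_healthy, design$n_cells_diabetic))
  out <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    nj <- design$granules_per_cell[j]
    w <- if (v > 0) stats::rgamma(1, shape = 1 / v, scale = v) else 1
    z <- assign_frailties(nj, pi_of(tr, Xcell[j]), tr$eta)
    u <- stats::runif(nj)
    te <- invert_cumulative_hazard(u, z * w, tr, Xcell[j], protocol)
    out[[j]] <- data.frame(cell_id = sprintf("cell%02d", j),
                           granule_id = sprintf("g%04d", seq_len(nj)),
                           time = te$time, event = te$event,
                           diabetic = Xcell[j])
  }
  gd <- granule_data(do.call(rbind, out), protocol)
  attr(gd, "design") <- design
  gd
}

#' Write the simulation-truth sidecar
#'
#' Records the generating design next to a simulated event CSV so the
#' provenance of synthetic data is explicit (granule counts and
#' heterogeneity are conventions of the generator, not measured facts).
#'
#' @param design A [simulation_design()].
#' @param file Output path (YAML).
#' @export
write_truth_sidecar <- function(design, file) {
  tr <- design$truth
  yaml::write_yaml(list(
    n_cells_healthy = design$n_cells_healthy,
    n_cells_diabetic = design$n_cells_diabetic,
    granules_per_cell = design$granules_per_cell,
    cell_heterogeneity_variance = design$cell_heterogeneity_variance,
    truth = unclass(tr)), file)
  invisible(file)
}
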