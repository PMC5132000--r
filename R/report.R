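#' Table-style report of a frailty fit with cluster-adjusted inference
#'
#' One row per reported parameter of the discrete-frailty model:
#' point estimates on the natural scale, profile-likelihood confidence
#' intervals from the adjusted log-likelihood, adjusted
#' likelihood-ratio p-values, and the corresponding naive
#' (clustering-ignoring) p-values. Nulls: equal pulse and between-pulse
#' rates for the `rho2` row, zero covariate effect for `beta2`, unit
#' frailty ratio for `eta`, and the boundary null \eqn{\pi_X = 0}
#' (one-sided mixture reference) for the pool probabilities.
#'
#' @param fit A `frailty_fit`.
#' @param level Confidence level, default 0.95.
#' @return Data frame with columns `parameter`, `estimate`, `lower`,
#'   `upper`, `p`, `p_naive`, `converged`.
#' @export
frailty_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "frailty_fit"))
  adj <- adjusted_inference(fit, adjust = TRUE)
  nai <- adjusted_inference(fit, adjust = FALSE)
  th <- fit$theta_hat
  trans <- list(alpha1 = exp, alpha2 = exp, beta2 = identity,
                log_eta = exp, pi0 = identity, pi1 = identity)
  labels <- c(alpha1 = "rho1", alpha2 = "rho2", beta2 = "beta2",
              log_eta = "eta", pi0 = "pi0", pi1 = "pi1")
  tests <- list(
    alpha1 = NULL,
    alpha2 = list(equal = c("alpha1", "alpha2"), boundary = FALSE),
    beta2 = list(fix = "beta2", value = 0, boundary = FALSE),
    log_eta = list(fix = "log_eta", value = 0, boundary = FALSE),
    pi0 = list(fix = "pi0", value = 0, boundary = TRUE),
    pi1 = list(fix = "pi1", value = 0, boundary = TRUE))
  rows <- lapply(theta_names, function(nm) {
    f <- trans[[nm]]
    ci <- suppressWarnings(profile_ci(adj, nm, level))
    tst <- tests[[nm]]
    p <- p_naive <- NA_real_
    if (!is.null(tst)) {
      run <- function(a) {
        if (!is.null(tst$equal))
          lrt_adjusted(a, equal = tst$equal)$p_value
        else lrt_adjusted(a, param = tst$fix, null_value = tst$value,
                          boundary = tst$boundary)$p_value
      }
      p <- run(adj); p_naive <- run(nai)
    }
    data.frame(parameter = labels[[nm]], estimate = f(th[[nm]]),
               lower = f(ci[[1]]), upper = f(ci[[2]]),
               p = p, p_naive = p_naive, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined results report
#'
#' Assembles the piecewise-exponential (Poisson) and frailty-model
#' report tables. Non-converged fits are flagged in the `converged`
#' column rather than silently reported.
#'
#' @param poisson_fit A `pexp_fit`, or `NULL`.
#' @param frailty_fit A `frailty_fit`, or `NULL`.
#' @param level Confidence level.
#' @return Named list of data frames (`poisson`, `frailty`; absent
#'   fits are dropped).
#' @export
results_table <- function(poisson_fit = NULL, frailty_fit = NULL,
                          level = 0.95) {
  out <- list()
  if (!is.null(poisson_fit)) {
    tb <- summary(poisson_fit, level = level)
    tb$converged <- poisson_fit$converged
    out$poisson <- tb
  }
  if (!is.null(frailty_fit))
    out$frailty <- frailty_table(frailty_fit, level = level)
  out
}

#' Docked-granule count from capacitance and density
#'
#' Membrane area is total cell capacitance divided by specific membrane
#' capacitance; multiplying by the surface density of docked granules
#' gives the expected docked-granule count per cell.
#'
#' @param capacitance_pF Whole-cell membrane capacitance (pF).
#' @param specific_capacitance_fF_um2 Specific membrane capacitance
#'   (fF per square micron).
#' @param density_per_um2 Docked granules per square micron of
#'   membrane.
#' @return Estimated docked granules per cell.
#' @export
docked_granule_count <- function(capacitance_pF = 10,
                                 specific_capacitance_fF_um2 = 10,
                                 density_per_um2 = 0.8) {
  stopifnot(capacitance_pF > 0, specific_capacitance_fF_um2 > 0,
            density_per_um2 >= 0)
  area_um2 <- capacitance_pF * 1000 / specific_capacitance_fF_um2
  area_um2 * density_per_um2
}

#' IRP size in granules
#'
#' The immediately releasable pool as a count: docked granules times
#' the estimated IRP probability.
#'
#' @param n_docked Docked granules per cell.
#' @param pi_x Estimated IRP probability.
#' @return Expected IRP granule count per cell.
#' @export
irp_granule_count <- function(n_docked, pi_x) {
  stopifnot(n_docked >= 0, pi_x >= 0, pi_x <= 1)
  n_docked * pi_x
}
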