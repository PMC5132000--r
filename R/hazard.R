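#' Piecewise-constant hazard parameters (Poisson formulation)
#'
#' Parameters of the time-varying piecewise-constant hazard
#' \deqn{\mu(t \mid X) = \exp(\alpha_k + \beta_k X)}
#' where segment k = 0 is the first pulse, k = 1 a later pulse and
#' k = 2 the rest intervals, and X is the binary diabetes covariate.
#' The baseline rates are \eqn{\rho_k = e^{\alpha_k}} (per second).
#'
#' @param alpha Numeric length 3: log baseline rates (log s^-1) for
#'   (first pulse, later pulse, between).
#' @param beta Numeric length 3: log hazard ratios of the covariate per
#'   segment. Default all zero.
#' @return Object of class `poisson_params`.
#' @export
poisson_params <- function(alpha, beta = c(0, 0, 0)) {
  stopifnot(is.numeric(alpha), length(alpha) == 3, all(is.finite(alpha)),
            is.numeric(beta), length(beta) == 3, all(is.finite(beta)))
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "poisson_params")
}

#' Discrete IRP frailty-model parameters
#'
#' Parameters of the two-point frailty model: conditionally on the
#' frailty Z, the hazard is \eqn{Z \mu_0(t|X)} with baseline
#' \eqn{\mu_0 = e^{\alpha_1}} during any pulse (identical across pulses
#' by model constraint) and \eqn{e^{\alpha_2 + \beta_2 X}} between
#' pulses. Z equals `eta` with probability `pi_X` (the granule belongs
#' to the immediately releasable pool, IRP) and 1 otherwise.
#'
#' @param alpha1 Log baseline rate during pulses (log s^-1).
#' @param alpha2 Log baseline rate between pulses (log s^-1).
#' @param beta2 Log hazard ratio of the covariate between pulses.
#' @param eta Frailty ratio (> 0; IRP granules release `eta`-fold faster).
#' @param pi0,pi1 IRP probabilities in covariate groups X = 0 and X = 1.
#' @return Object of class `frailty_params`.
#' @export
frailty_params <- function(alpha1, alpha2, beta2 = 0, eta = 1,
                           pi0 = 0, pi1 = pi0) {
  stopifnot(is.finite(alpha1), is.finite(alpha2), is.finite(beta2),
            is.finite(eta), eta > 0,
            pi0 >= 0, pi0 <= 1, pi1 >= 0, pi1 <= 1)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta2 = beta2,
                 eta = eta, pi0 = pi0, pi1 = pi1),
            class = "frailty_params")
}

pi_of <- function(params, X) ifelse(X > 0, params$pi1, params$pi0)

# Baseline rate per protocol segment row, given covariate X (scalar)
segment_rates <- function(params, X, segments) {
  X <- as.numeric(X)
  if (inherits(params, "poisson_params")) {
    k <- as.integer(segments) # 1,2,3
    exp(params$alpha[k] + params$beta[k] * X)
  } else if (inherits(params, "frailty_params")) {
    ifelse(segments == "between",
           exp(params$alpha2 + params$beta2 * X),
           exp(params$alpha1))
  } else stop("unsupported parameter object")
}

#' Hazard at a time point
#'
#' Evaluates \eqn{\mu(t | X, Z) = z\,\mu_0(t | X)} with the baseline
#' taken from the segment containing `t` (half-open pulse intervals).
#' For the Poisson (no-frailty) model use `z = 1`.
#'
#' @param t Times in `[0, observation_end)`.
#' @param params [poisson_params()] or [frailty_params()].
#' @param X Covariate value (0/1), scalar.
#' @param z Frailty multiplier (scalar, > 0); 1 or `eta` in the frailty
#'   model.
#' @param protocol A [stim_protocol()].
#' @return Hazard rates (s^-1), same length as `t`.
#' @export
hazard_at <- function(t, params, X = 0, z = 1, protocol = stim_protocol()) {
  stopifnot(z > 0)
  if (any(t < 0)) stop("negative times are outside the model domain")
  z * segment_rates(params, X, segment_of(t, protocol))
}

#' Cumulative baseline hazard
#'
#' Closed-form \eqn{M_0(t|X) = \int_0^t \mu_0(s|X)\,ds}: the sum of
#' rate times overlap length over the protocol segments intersecting
#' `[0, t)`. Continuous, nondecreasing and piecewise linear in `t`.
#'
#' @inheritParams hazard_at
#' @param t Times in `[0, observation_end]`, vectorized.
#' @return Cumulative hazards (dimensionless), same length as `t`.
#' @export
cumulative_baseline_hazard <- function(t, params, X = 0,
                                       protocol = stim_protocol()) {
  if (any(t < 0) || any(t > protocol$observation_end))
    stop("times must lie in [0, observation_end]")
  sb <- segment_breaks(protocol)
  rates <- segment_rates(params, X, sb$segment)
  # overlap of [0, t) with each [start, end): outer over t
  ov <- pmax(0, outer(t, sb$end, pmin) - rep(sb$start, each = length(t)))
  dim(ov) <- c(length(t), nrow(sb))
  as.numeric(ov %*% rates)
}

#' Marginal survival under the discrete frailty model
#'
#' The frailty-averaged survival function
#' \deqn{S(t|X) = \pi_X e^{-\eta M_0(t|X)} + (1-\pi_X) e^{-M_0(t|X)},}
#' a two-component mixture of IRP and non-IRP survival curves.
#'
#' @inheritParams cumulative_baseline_hazard
#' @param params A [frailty_params()].
#' @return Survival probabilities, same length as `t`.
#' @export
marginal_survival <- function(t, X = 0, params, protocol = stim_protocol()) {
  stopifnot(inherits(params, "frailty_params"))
  M0 <- cumulative_baseline_hazard(t, params, X, protocol)
  p <- pi_of(params, X)
  p * exp(-params$eta * M0) + (1 - p) * exp(-M0)
}

#' Survival / incidence curve container
#'
#' @param times Nondecreasing numeric times (s).
#' @param values Probabilities in `[0, 1]`; nonincreasing for
#'   `kind = "survival"`, nondecreasing for `kind = "incidence"`.
#' @param kind `"survival"` or `"incidence"`.
#' @return Object of class `survival_curve` (a data frame with columns
#'   `time` and `value`).
#' @export
survival_curve <- function(times, values, kind = c("survival", "incidence")) {
  kind <- match.arg(kind)
  stopifnot(length(times) == length(values),
            !is.unsorted(times),
            all(values >= -1e-12 & values <= 1 + 1e-12))
  tol <- 1e-9
  d <- diff(values)
  if (kind == "survival" && any(d > tol))
    stop("survival curve must be nonincreasing")
  if (kind == "incidence" && any(d < -tol))
    stop("incidence curve must be nondecreasing")
  structure(data.frame(time = times, value = pmin(pmax(values, 0), 1)),
            kind = kind, class = c("survival_curve", "data.frame"))
}

#' Decomposition of the cumulative incidence into frailty components
#'
#' Returns the marginal cumulative incidence \eqn{1 - S(t|X)} together
#' with its IRP component \eqn{\pi_X (1 - e^{-\eta M_0})} and non-IRP
#' component \eqn{(1-\pi_X)(1 - e^{-M_0})}. The two components sum to
#' the marginal at every time.
#'
#' @param grid Numeric time grid within `[0, observation_end]`.
#' @inheritParams marginal_survival
#' @return Named list of three [survival_curve()]s (`marginal`, `irp`,
#'   `non_irp`), all of kind `"incidence"`.
#' @export
incidence_components <- function(grid, X = 0, params,
                                 protocol = stim_protocol()) {
  stopifnot(inherits(params, "frailty_params"))
  M0 <- cumulative_baseline_hazard(grid, params, X, protocol)
  p <- pi_of(params, X)
  irp <- p * (1 - exp(-params$eta * M0))
  non <- (1 - p) * (1 - exp(-M0))
  list(marginal = survival_curve(grid, irp + non, "incidence"),
       irp      = survival_curve(grid, irp, "incidence"),
       non_irp  = survival_curve(grid, non, "incidence"))
}
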