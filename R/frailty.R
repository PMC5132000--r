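# Working parameterization of the frailty model:
#   theta = (alpha1, alpha2, beta2, log_eta, pi0, pi1)
# log for the rates and the frailty ratio symmetrizes the likelihood;
# the pool probabilities stay on the natural scale so that the boundary
# null pi_X = 0 is a finite working value (required by the adjusted
# boundary likelihood-ratio test).
theta_names <- c("alpha1", "alpha2", "beta2", "log_eta", "pi0", "pi1")

#' Working-scale parameter vector of the frailty model
#'
#' Maps between a [frailty_params()] object and the working vector
#' \eqn{\theta = (\alpha_1, \alpha_2, \beta_2, \log\eta, \pi_0, \pi_1)}
#' used for optimization and inference.
#'
#' @param params A [frailty_params()].
#' @return `as_working_theta()`: named numeric vector of length 6.
#' @export
as_working_theta <- function(params) {
  stopifnot(inherits(params, "frailty_params"))
  stats::setNames(c(params$alpha1, params$alpha2, params$beta2,
                    log(params$eta), params$pi0, params$pi1), theta_names)
}

#' @rdname as_working_theta
#' @param theta Named or positional numeric vector of length 6 on the
#'   working scale.
#' @return `from_working_theta()`: a [frailty_params()].
#' @export
from_working_theta <- function(theta) {
  stopifnot(length(theta) == 6)
  frailty_params(alpha1 = theta[[1]], alpha2 = theta[[2]],
                 beta2 = theta[[3]], eta = exp(theta[[4]]),
                 pi0 = theta[[5]], pi1 = theta[[6]])
}

# Per-granule sufficient statistics for the frailty likelihood:
# exposure during pulses (Ep) and between pulses (Eb), event indicator,
# event segment (pulse/between) and covariate. Granules with identical
# statistics are collapsed with multiplicity weights (all censored
# granules of a covariate group share one row), which makes likelihood
# evaluation O(#events) rather than O(#granules).
frailty_precompute <- function(gd) {
  stopifnot(inherits(gd, "granule_data"))
  d <- gd$data
  sb <- segment_breaks(gd$protocol)
  n <- nrow(d)
  ov <- pmax(0, outer(d$time, sb$end, pmin) - rep(sb$start, each = n))
  dim(ov) <- c(n, nrow(sb))
  pulse <- sb$segment != "between"
  Ep <- rowSums(ov[, pulse, drop = FALSE])
  Eb <- rowSums(ov[, !pulse, drop = FALSE])
  seg <- event_segment(d$time, gd$protocol)
  ev_pulse <- as.integer(d$event == 1 & seg != "between")
  key <- paste(signif(Ep, 12), signif(Eb, 12), d$event, ev_pulse,
               d$diabetic)
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(Ep = Ep[first], Eb = Eb[first], d = d$event[first],
       ev_pulse = ev_pulse[first], X = d$diabetic[first], w = w,
       cluster = NULL, n = n)
}

# uncollapsed version retaining cluster labels (for per-cluster scores)
frailty_precompute_by_cluster <- function(gd) {
  pre <- frailty_precompute(gd)
  d <- gd$data
  sb <- segment_breaks(gd$protocol)
  n <- nrow(d)
  ov <- pmax(0, outer(d$time, sb$end, pmin) - rep(sb$start, each = n))
  dim(ov) <- c(n, nrow(sb))
  pulse <- sb$segment != "between"
  seg <- event_segment(d$time, gd$protocol)
  list(Ep = rowSums(ov[, pulse, drop = FALSE]),
       Eb = rowSums(ov[, !pulse, drop = FALSE]),
       d = d$event, ev_pulse = as.integer(d$event == 1 & seg != "between"),
       X = d$diabetic, w = rep(1, n), cluster = d$cell_id, n = n)
}

# Per-row marginal log-likelihood contributions (Eq.-style mixture over
# the two frailty atoms) and, optionally, the analytic gradient.
# Stable for large eta*M0: terms are exponentiated relative to their max.
# pi values outside [0, 1] are tolerated as long as the mixture stays
# positive (needed when the adjusted-likelihood transform maps a working
# point slightly outside the natural domain); otherwise -Inf.
frailty_ll_rows <- function(theta, pre, gradient = FALSE) {
  a1 <- theta[[1]]; a2 <- theta[[2]]; b2 <- theta[[3]]
  lh <- theta[[4]]; eta <- exp(lh)
  p <- ifelse(pre$X > 0, theta[[6]], theta[[5]])
  rp <- exp(a1)
  rb <- exp(a2 + b2 * pre$X)
  M0 <- rp * pre$Ep + rb * pre$Eb
  lrate <- ifelse(pre$ev_pulse == 1, a1, a2 + b2 * pre$X)
  t1 <- pre$d * lh - eta * M0    # log of eta^d e^{-eta M0}
  t2 <- -M0
  m <- pmax(t1, t2)
  e1 <- exp(t1 - m); e2 <- exp(t2 - m)
  mix <- p * e1 + (1 - p) * e2
  if (any(mix <= 0) || any(!is.finite(mix)))
    return(list(ll = rep(-Inf, length(M0))))
  ll <- pre$d * lrate + m + log(mix)
  out <- list(ll = ll)
  if (gradient) {
    wA <- p * e1 / mix           # posterior weight of the IRP atom
    wB <- 1 - wA
    dldM <- -(wA * eta + wB)
    g <- cbind(
      alpha1 = pre$d * pre$ev_pulse + dldM * rp * pre$Ep,
      alpha2 = pre$d * (1 - pre$ev_pulse) + dldM * rb * pre$Eb,
      beta2 = pre$X * (pre$d * (1 - pre$ev_pulse) + dldM * rb * pre$Eb),
      log_eta = wA * (pre$d - eta * M0),
      pi0 = ifelse(pre$X > 0, 0, (e1 - e2) / mix),
      pi1 = ifelse(pre$X > 0, (e1 - e2) / mix, 0))
    out$grad <- g
  }
  out
}

#' Marginal independence log-likelihood of the frailty model
#'
#' The working-independence log-likelihood obtained by averaging each
#' granule's conditional likelihood over the two-point frailty
#' distribution:
#' \deqn{\ell_{ij} = \log\left[\mu_0(t|X)^d \left(\pi_X \eta^d
#'   e^{-\eta M_0(t|X)} + (1-\pi_X) e^{-M_0(t|X)}\right)\right].}
#' Clustering is ignored here (the "independence" in the name); valid
#' variances and tests come from [sandwich_variance()] and
#' [build_adjustment()].
#'
#' @param theta Working-scale vector (see [as_working_theta()]).
#' @param gd A [granule_data()].
#' @param by_cluster If `TRUE`, return the per-cluster contributions
#'   (named vector summing to the total) instead of the total.
#' @return Log-likelihood value, or per-cluster vector.
#' @export
loglik_independence <- function(theta, gd, by_cluster = FALSE) {
  if (by_cluster) {
    pre <- frailty_precompute_by_cluster(gd)
    rows <- frailty_ll_rows(theta, pre)
    if (!all(is.finite(rows$ll))) {
      bad <- which(!is.finite(rows$ll))[1]
      stop("non-finite likelihood contribution for granule ",
           gd$data$granule_id[bad], " of ", gd$data$cell_id[bad])
    }
    return(drop(rowsum(rows$ll, pre$cluster)[, 1]))
  }
  pre <- frailty_precompute(gd)
  val <- sum(frailty_ll_rows(theta, pre)$ll * pre$w)
  if (!is.finite(val)) stop("non-finite independence log-likelihood")
  val
}

# negative loglik + gradient closures over a precomputed structure;
# invalid points get a large finite penalty so bounded quasi-Newton
# line searches can recover
frailty_objective <- function(pre) {
  list(
    fn = function(theta) {
      v <- sum(frailty_ll_rows(theta, pre)$ll * pre$w)
      if (!is.finite(v)) 1e10 else -v
    },
    gr = function(theta) {
      r <- frailty_ll_rows(theta, pre, gradient = TRUE)
      if (is.null(r$grad) || !all(is.finite(r$grad))) rep(0, 6)
      else -colSums(r$grad * pre$w)
    })
}

#' Default starting grid for the frailty fit
#'
#' The no-frailty (piecewise-exponential) fit of
#' \eqn{(\alpha_1, \alpha_2, \beta_2)} crossed with
#' \eqn{\eta \in \{10, 100, 1000\}} and \eqn{\pi \in \{0.005, 0.02,
#' 0.1\}} (same value for both groups at the start).
#'
#' @param gd A [granule_data()].
#' @param eta_grid,pi_grid Start values for the frailty ratio and pool
#'   probability.
#' @return List of working-scale start vectors.
#' @export
frailty_starts <- function(gd, eta_grid = c(10, 100, 1000),
                           pi_grid = c(0.005, 0.02, 0.1)) {
  base <- fit_piecewise_exponential(gd, first_pulse_distinct = FALSE)
  a1 <- base$params$alpha[2]
  a2 <- base$params$alpha[3]
  b2 <- base$params$beta[3]
  out <- list()
  for (e in eta_grid) for (p in pi_grid)
    out[[length(out) + 1]] <-
      stats::setNames(c(a1, a2, b2, log(e), p, p), theta_names)
  out
}

#' Maximum-likelihood fit of the discrete frailty model
#'
#' Maximizes the marginal independence log-likelihood over the working
#' parameter vector from multiple starting points (bounded quasi-Newton
#' via [stats::nlminb()] with the analytic gradient), keeps the best
#' local optimum, and computes the observed Hessian there
#' (central-difference Jacobian of the analytic gradient, with
#' Richardson extrapolation, symmetrized).
#'
#' @param gd A [granule_data()]; needs at least one event in each
#'   covariate group for \eqn{\beta_2} to be identifiable.
#' @param starts List of working-scale start vectors; default
#'   [frailty_starts()].
#' @param tol Relative convergence tolerance of the optimizer.
#' @return Object of class `frailty_fit`: `theta_hat` (working scale),
#'   `params` (natural scale), `loglik`, `hessian` (of \eqn{\ell_I} at
#'   the optimum), `converged`, `boundary` (named logical: \eqn{\hat\pi}
#'   within 1e-6 of 0 or 1), `starts` (data frame of start points and
#'   attained objectives), `gradient_norm`.
#' @export
fit_frailty <- function(gd, starts = NULL, tol = 1e-10) {
  stopifnot(inherits(gd, "granule_data"))
  for (x in unique(gd$data$diabetic))
    if (sum(gd$data$event[gd$data$diabetic == x]) == 0)
      stop("no events in covariate group X = ", x,
           "; beta2 is not identifiable")
  if (is.null(starts)) starts <- frailty_starts(gd)
  pre <- frailty_precompute(gd)
  obj <- frailty_objective(pre)
  lower <- c(-Inf, -Inf, -Inf, -Inf, 0, 0)
  upper <- c(Inf, Inf, Inf, Inf, 1, 1)
  fits <- lapply(starts, function(s)
    tryCatch(stats::nlminb(s, obj$fn, gradient = obj$gr,
                           lower = lower, upper = upper,
                           control = list(rel.tol = tol, iter.max = 500,
                                          eval.max = 1000)),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("all starting points failed to converge")
  objs <- vapply(fits, function(f) if (is.null(f)) Inf else f$objective, 0)
  best <- fits[[which.min(objs)]]
  theta <- stats::setNames(best$par, theta_names)
  H <- fd_jacobian(function(th) -obj$gr(th), theta)
  H <- (H + t(H)) / 2
  boundary <- c(pi0 = theta[[5]] < 1e-6 || theta[[5]] > 1 - 1e-6,
                pi1 = theta[[6]] < 1e-6 || theta[[6]] > 1 - 1e-6)
  # gradient norm over coordinates not pinned at a bound
  free <- c(TRUE, TRUE, TRUE, TRUE, !boundary)
  gnorm <- sqrt(sum(obj$gr(theta)[free]^2))
  if (any(boundary))
    message("boundary solution: ",
            paste(names(boundary)[boundary], collapse = ", "),
            " at the edge of [0, 1]")
  start_tab <- data.frame(do.call(rbind, starts),
                          objective = -objs[seq_along(starts)])
  structure(list(theta_hat = theta, params = from_working_theta(theta),
                 loglik = -best$objective, hessian = H,
                 converged = gnorm < 1e-5 * max(1, abs(best$objective)),
                 boundary = boundary, gradient_norm = gnorm,
                 starts = start_tab, data = gd),
            class = "frailty_fit")
}

#' @export
print.frailty_fit <- function(x, ...) {
  cat("Discrete IRP-frailty model fit\n")
  cat("log-likelihood (independence):", format(x$loglik), "\n")
  p <- x$params
  est <- c(rho1 = exp(p$alpha1), rho2 = exp(p$alpha2), beta2 = p$beta2,
           eta = p$eta, pi0 = p$pi0, pi1 = p$pi1)
  print(signif(est, 4))
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}
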