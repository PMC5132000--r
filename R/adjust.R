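#' Per-cluster score vectors
#'
#' Numerical gradients (central differences with Richardson
#' extrapolation) of each cluster's summed log-likelihood contribution.
#' At the maximum-likelihood estimate the scores sum to (numerically)
#' zero.
#'
#' @param loglik_by_cluster Function mapping a working parameter vector
#'   to the named vector of per-cluster log-likelihood contributions.
#' @param theta Working-scale parameter vector (at or near the MLE).
#' @return J x p matrix of score vectors, one row per cluster.
#' @export
score_by_cluster <- function(loglik_by_cluster, theta) {
  U <- fd_jacobian(loglik_by_cluster, theta)
  base <- loglik_by_cluster(theta)
  rownames(U) <- names(base)
  bad <- !apply(is.finite(U), 1, all)
  if (any(bad))
    stop("non-finite score for cluster(s): ",
         paste(rownames(U)[bad], collapse = ", "))
  U
}

#' Analytic per-cluster scores of a frailty fit
#'
#' Exact per-granule gradients of the marginal independence
#' log-likelihood, summed within cells. Used by the fitted pipeline;
#' [score_by_cluster()] is the generic numerical route.
#'
#' @param fit A `frailty_fit`.
#' @param theta Working-scale vector; defaults to the fit's MLE.
#' @return J x 6 matrix of cluster score vectors.
#' @export
cluster_scores <- function(fit, theta = fit$theta_hat) {
  pre <- frailty_precompute_by_cluster(fit$data)
  r <- frailty_ll_rows(theta, pre, gradient = TRUE)
  if (is.null(r$grad) || !all(is.finite(r$grad)))
    stop("non-finite score contributions at theta")
  U <- rowsum(r$grad, pre$cluster)
  colnames(U) <- theta_names
  U
}

#' Cluster-robust sandwich variance
#'
#' \deqn{\hat R = \hat H^{-1} \hat V \hat H^{-1}, \qquad
#'   \hat V = \sum_j U_j U_j',}
#' where \eqn{\hat H} is the observed Hessian of the independence
#' log-likelihood at the MLE and \eqn{U_j} the per-cluster scores.
#' Valid under within-cluster dependence that the independence
#' likelihood ignores.
#'
#' @param H Observed Hessian (p x p, negative definite at an interior
#'   optimum).
#' @param scores J x p matrix of cluster score vectors.
#' @return List with `H`, `V`, `R` (sandwich variance) and `robust_se`.
#' @export
sandwich_variance <- function(H, scores) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H), ncol(scores) == nrow(H))
  rc <- rcond(H)
  if (!is.finite(rc) || rc < 1e-14)
    stop("Hessian is numerically singular (reciprocal condition number ",
         format(rc), ")")
  V <- crossprod(scores)
  Hi <- solve(H)
  R <- Hi %*% V %*% Hi
  R <- (R + t(R)) / 2
  dimnames(R) <- dimnames(H)
  list(H = H, V = V, R = R, robust_se = sqrt(pmax(diag(R), 0)))
}

# symmetric (spectral) positive-definite square root
spectral_sqrt <- function(A, label = "matrix") {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  if (any(e$values <= 0))
    stop(label, " is not positive definite (min eigenvalue ",
         format(min(e$values)), "); the optimum may be on a boundary or ",
         "there may be too few clusters")
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

#' Chandler-Bate adjusted log-likelihood
#'
#' Builds the adjusted log-likelihood
#' \deqn{\ell_A(\theta) = \ell_I(\hat\theta_I + C(\theta -
#'   \hat\theta_I)), \quad C = N^{-1} N_A,}
#' with \eqn{N' N = -\hat H} and \eqn{N_A' N_A = R^{-1}}, the matrix
#' square roots taken spectrally from the positive-definite forms
#' (observed-information sign convention). \eqn{\ell_A} has the same
#' maximum as \eqn{\ell_I}, but its curvature there is \eqn{-R^{-1}}:
#' likelihood-ratio statistics computed from it account for clustering.
#'
#' @param H Observed Hessian of the independence log-likelihood at the
#'   MLE.
#' @param R Sandwich variance from [sandwich_variance()].
#' @param loglik Function: working-scale vector -> independence
#'   log-likelihood.
#' @param theta_hat The MLE of the independence log-likelihood.
#' @return Object of class `adjusted_loglik` with elements `theta_hat`,
#'   `C`, `H`, `R`, `loglik_I`, `loglik_A`.
#' @export
build_adjustment <- function(H, R, loglik, theta_hat) {
  N <- spectral_sqrt(-H, "-H (observed information)")
  NA_ <- spectral_sqrt(solve(R), "inverse sandwich variance")
  C <- solve(N) %*% NA_
  dimnames(C) <- dimnames(H)
  force(loglik); force(theta_hat)
  loglik_A <- function(theta)
    loglik(as.numeric(theta_hat + C %*% (theta - theta_hat)))
  structure(list(theta_hat = theta_hat, C = C, H = H, R = R,
                 loglik_I = loglik, loglik_A = loglik_A),
            class = "adjusted_loglik")
}

#' Adjusted inference objects for a frailty fit
#'
#' Convenience wrapper: analytic cluster scores, sandwich variance and
#' the adjusted log-likelihood for a fitted frailty model. With
#' `adjust = FALSE` the identity adjustment is returned (\eqn{R =
#' (-\hat H)^{-1}}, so \eqn{\ell_A \equiv \ell_I}): this is the naive,
#' clustering-ignoring likelihood used for the "no clustering"
#' comparison columns.
#'
#' @param fit A `frailty_fit`.
#' @param adjust Use the cluster sandwich (`TRUE`, default) or the
#'   naive identity adjustment.
#' @return An `adjusted_loglik`; the sandwich pieces are attached as
#'   attribute `"sandwich"`.
#' @export
adjusted_inference <- function(fit, adjust = TRUE) {
  stopifnot(inherits(fit, "frailty_fit"))
  pre <- frailty_precompute(fit$data)
  ll <- function(theta) sum(frailty_ll_rows(theta, pre)$ll * pre$w)
  H <- fit$hessian
  if (adjust) {
    U <- cluster_scores(fit)
    sw <- sandwich_variance(H, U)
  } else {
    sw <- list(H = H, V = -H, R = solve(-H),
               robust_se = sqrt(pmax(diag(solve(-H)), 0)))
  }
  adj <- build_adjustment(H, sw$R, ll, fit$theta_hat)
  attr(adj, "sandwich") <- sw
  adj
}

# maximize loglik_A over theta subject to a constraint; free coordinates
# are unconstrained on the working scale (the inner transform may step
# slightly outside the natural pi domain, which the likelihood treats
# as -Inf via a finite penalty)
constrained_max <- function(adj, fix = NULL, value = NULL, equal = NULL,
                            start = NULL) {
  p <- length(adj$theta_hat)
  if (!is.null(fix)) {
    fix <- if (is.character(fix)) match(fix, theta_names) else fix
    free <- setdiff(seq_len(p), fix)
    expand <- function(par) {
      th <- numeric(p); th[free] <- par; th[fix] <- value; th
    }
    start_free <- (if (is.null(start)) adj$theta_hat else start)[free]
  } else if (!is.null(equal)) {
    equal <- if (is.character(equal)) match(equal, theta_names) else equal
    stopifnot(length(equal) == 2)
    free <- setdiff(seq_len(p), equal[2])
    expand <- function(par) {
      th <- numeric(p); th[free] <- par; th[equal[2]] <- th[equal[1]]; th
    }
    s0 <- if (is.null(start)) adj$theta_hat else start
    s0[equal[1]] <- mean(s0[equal])
    start_free <- s0[free]
  } else stop("supply `fix` + `value` or `equal`")
  nll <- function(par) {
    v <- adj$loglik_A(expand(par))
    if (!is.finite(v)) 1e10 else -v
  }
  ctrl <- list(rel.tol = 1e-10, iter.max = 500, eval.max = 1500)
  opt <- stats::nlminb(start_free, nll, control = ctrl)
  if (opt$convergence != 0) { # restart once from the candidate optimum
    opt2 <- stats::nlminb(opt$par, nll, control = ctrl)
    if (opt2$objective <= opt$objective) opt <- opt2
  }
  ok <- opt$convergence == 0 ||
    grepl("relative convergence|X-convergence", opt$message)
  list(theta = expand(opt$par), loglik = -opt$objective, converged = ok)
}

#' Adjusted likelihood-ratio test
#'
#' \eqn{\Lambda_A = 2(\ell_A(\hat\theta_I) - \ell_A(\tilde\theta))},
#' where \eqn{\tilde\theta} maximizes the adjusted log-likelihood under
#' the null constraint. Interior nulls are referred to \eqn{\chi^2_1};
#' nulls on the boundary of the parameter space (a pool probability
#' equal to 0) to the mixture \eqn{(\chi^2_0 + \chi^2_1)/2}, i.e. a
#' one-sided test.
#'
#' @param adj An `adjusted_loglik` (from [build_adjustment()] or
#'   [adjusted_inference()]).
#' @param param Working-scale parameter name or index to constrain
#'   (ignored when `equal` is given).
#' @param null_value Null value of that coordinate. Default 0.
#' @param boundary Is the null on the boundary of the parameter space?
#' @param equal Length-2 names/indices for an equality null
#'   \eqn{\theta_i = \theta_j} (e.g. equal pulse and between rates).
#' @return List with `statistic`, `p_value`, `df`, `boundary`,
#'   `theta_null` (constrained optimum, working scale),
#'   `loglik_null`.
#' @export
lrt_adjusted <- function(adj, param = NULL, null_value = 0,
                         boundary = FALSE, equal = NULL) {
  stopifnot(inherits(adj, "adjusted_loglik"))
  l_hat <- adj$loglik_A(adj$theta_hat)
  # when the MLE already satisfies the null (e.g. a pool probability
  # estimated exactly at the boundary), the statistic is identically 0
  k <- if (is.character(param)) match(param, theta_names) else param
  satisfied <- if (is.null(equal))
    abs(adj$theta_hat[k] - null_value) < 1e-9
  else {
    eq <- if (is.character(equal)) match(equal, theta_names) else equal
    abs(diff(adj$theta_hat[eq])) < 1e-9
  }
  if (satisfied) {
    con <- list(theta = adj$theta_hat, loglik = l_hat, converged = TRUE)
  } else {
    con <- if (is.null(equal))
      constrained_max(adj, fix = param, value = null_value)
    else constrained_max(adj, equal = equal)
    if (!con$converged)
      warning("constrained maximization did not report clean convergence")
  }
  lambda <- 2 * (l_hat - con$loglik)
  if (lambda < -1e-6)
    stop("constrained optimum exceeds the unconstrained one (Lambda = ",
         format(lambda), "); optimization failure")
  lambda <- max(lambda, 0)
  if (lambda < 1e-8) lambda <- 0
  p <- if (boundary)
    0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE) +
      0.5 * (lambda <= 0)
  else stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  list(statistic = lambda, p_value = p, df = 1, boundary = boundary,
       theta_null = con$theta, loglik_null = con$loglik)
}

#' Profile-likelihood confidence interval from the adjusted likelihood
#'
#' Endpoints solve \eqn{2\{\ell_A(\hat\theta_I) - \max_{\text{nuisance}}
#' \ell_A\} = \chi^2_{1,\text{level}}} by root bracketing and bisection
#' (`uniroot`) on the working scale. Pool-probability coordinates are
#' clipped to `[0, 1]`; when the profile deviance at a natural bound has
#' not reached the threshold, that side is reported at the bound with a
#' warning (one-sided behavior near the boundary).
#'
#' @param adj An `adjusted_loglik`.
#' @param param Working-scale parameter name or index.
#' @param level Confidence level, default 0.95.
#' @return Numeric `c(lower, upper)` on the working scale, with
#'   attribute `"open"` flagging sides stopped at a bound.
#' @export
profile_ci <- function(adj, param, level = 0.95) {
  k <- if (is.character(param)) match(param, theta_names) else param
  stopifnot(!is.na(k), level > 0, level < 1)
  q <- stats::qchisq(level, df = 1)
  l_hat <- adj$loglik_A(adj$theta_hat)
  se <- sqrt(pmax(diag(adj$R), 0))[k]
  if (!is.finite(se) || se == 0) se <- 0.1 * max(1, abs(adj$theta_hat[k]))
  warm <- adj$theta_hat
  g <- function(c0) {
    con <- constrained_max(adj, fix = k, value = c0, start = warm)
    warm <<- con$theta
    2 * (l_hat - con$loglik) - q
  }
  bound <- if (k >= 5) c(0, 1) else c(-Inf, Inf)  # pi coordinates
  ends <- c(NA_real_, NA_real_)
  open <- c(lower = FALSE, upper = FALSE)
  for (side in 1:2) {
    sgn <- if (side == 1) -1 else 1
    warm <- adj$theta_hat
    lo <- adj$theta_hat[k]
    g_lo <- -q # profile deviance is 0 at the MLE
    hit <- NA_real_
    g_hit <- NA_real_
    for (step in se * 2^(0:7)) {
      cand <- adj$theta_hat[k] + sgn * step
      clipped <- min(max(cand, bound[1]), bound[2])
      val <- g(clipped)
      if (val > 0) { hit <- clipped; g_hit <- val; break }
      lo <- clipped; g_lo <- val
      if (clipped != cand) break # reached the natural bound
    }
    if (is.na(hit)) {
      ends[side] <- lo
      open[side] <- TRUE
    } else {
      r <- if (side == 1)
        stats::uniroot(g, lower = hit, upper = lo, f.lower = g_hit,
                       f.upper = g_lo, tol = 1e-6 * se)
      else
        stats::uniroot(g, lower = lo, upper = hit, f.lower = g_lo,
                       f.upper = g_hit, tol = 1e-6 * se)
      ends[side] <- r$root
    }
  }
  if (any(open))
    warning("profile interval for ", theta_names[k],
            " stopped at a parameter bound on the ",
            paste(names(open)[open], collapse = " and "),
            " side (one-sided behavior near the boundary)")
  structure(sort(ends), open = open, names = c("lower", "upper"))
}
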