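# rate of the segment containing t; an event recorded exactly at the end
# of observation (probability zero in continuous time, but legal input)
# uses the last segment's rate (left limit).
event_segment <- function(t, protocol) {
  sb <- segment_breaks(protocol)
  seg <- factor(rep(NA_character_, length(t)), levels = segment_levels)
  inside <- t < protocol$observation_end
  if (any(inside)) seg[inside] <- segment_of(t[inside], protocol)
  seg[!inside] <- sb$segment[nrow(sb)]
  seg
}

#' Episode splitting of granule follow-up
#'
#' Cuts each granule's follow-up `[0, t]` at every protocol segment
#' boundary and aggregates contiguous spells of the same segment class,
#' producing the long-format exposure/event table of the
#' piecewise-exponential (Poisson) representation. Per granule the
#' exposures sum exactly to the observed time, and the event (if any)
#' is attributed to the segment containing the event time.
#'
#' @param gd A [granule_data()].
#' @return Data frame with columns `cell_id`, `granule_id`, `segment`,
#'   `diabetic`, `exposure` (s), `events` (0/1). Rows with zero exposure
#'   and no event are dropped (they carry no likelihood information).
#' @export
episode_split <- function(gd) {
  stopifnot(inherits(gd, "granule_data"))
  d <- gd$data
  if (any(d$time <= 0)) stop("records with time <= 0 are invalid")
  sb <- segment_breaks(gd$protocol)
  n <- nrow(d)
  ov <- pmax(0, outer(d$time, sb$end, pmin) - rep(sb$start, each = n))
  dim(ov) <- c(n, nrow(sb))
  expo <- sapply(segment_levels, function(L)
    rowSums(ov[, sb$segment == L, drop = FALSE]))
  expo <- matrix(expo, nrow = n)
  ev_seg <- event_segment(d$time, gd$protocol)
  ev_seg[d$event == 0] <- NA
  out <- data.frame(
    cell_id = rep(d$cell_id, times = 3),
    granule_id = rep(d$granule_id, times = 3),
    segment = factor(rep(segment_levels, each = n),
                     levels = segment_levels),
    diabetic = rep(d$diabetic, times = 3),
    exposure = as.numeric(expo),
    events = as.integer(rep(segment_levels, each = n) ==
                          as.character(rep(ev_seg, times = 3))))
  out$events[is.na(out$events)] <- 0L
  out[out$exposure > 0 | out$events > 0, , drop = FALSE]
}

#' Survival-form log-likelihood of a piecewise-constant hazard model
#'
#' \eqn{\sum_{ij} d_{ij} \log\mu(t_{ij}|X_{ij}) - M(t_{ij}|X_{ij})},
#' the exact time-to-event log-likelihood of the piecewise-exponential
#' model (identical to the Poisson-table form because event indicators
#' are 0/1).
#'
#' @param params [poisson_params()] or [frailty_params()] (the latter is
#'   evaluated at frailty 1, i.e. the no-frailty baseline).
#' @param gd A [granule_data()].
#' @return Log-likelihood value.
#' @export
survival_loglik <- function(params, gd) {
  d <- gd$data
  ll <- 0
  for (x in unique(d$diabetic)) {
    i <- d$diabetic == x
    M <- cumulative_baseline_hazard(d$time[i], params, x, gd$protocol)
    seg <- event_segment(d$time[i], gd$protocol)
    rate <- segment_rates(params, x, seg)
    ll <- ll + sum(d$event[i] * log(rate[seq_along(rate)])) - sum(M)
  }
  ll
}

#' Fit the piecewise-exponential hazard model
#'
#' Maximum-likelihood fit of the time-varying piecewise-constant hazard
#' \eqn{\mu(t|X) = e^{\alpha_k + \beta_k X}} via its Poisson-regression
#' representation (`glm` with a log-exposure offset on the episode-split
#' table). Inference: naive (model-based) and cluster-robust sandwich
#' variances, the cluster being the cell.
#'
#' @param x A [granule_data()] or an episode-split table from
#'   [episode_split()].
#' @param first_pulse_distinct If `FALSE`, the first pulse shares its
#'   rate (and covariate effect) with later pulses (the constraint
#'   \eqn{\alpha_0 = \alpha_1} of the frailty model's baseline).
#' @param diabetes_effect `"by_segment"` (a separate \eqn{\beta_k} per
#'   segment) or `"none"` (all \eqn{\beta_k = 0}).
#' @return Object of class `pexp_fit` with elements `params`
#'   ([poisson_params()]), `loglik` (survival form), `coef`,
#'   `naive_vcov`, `robust_vcov`, `n_clusters`, `converged`,
#'   `non_identifiable`.
#' @export
fit_piecewise_exponential <- function(x, first_pulse_distinct = TRUE,
                                      diabetes_effect = c("by_segment",
                                                          "none")) {
  diabetes_effect <- match.arg(diabetes_effect)
  tab <- if (inherits(x, "granule_data")) episode_split(x) else x
  stopifnot(all(c("segment", "exposure", "events", "diabetic", "cell_id")
                %in% names(tab)))
  if (sum(tab$events) < 1) stop("no events in the data; rates not estimable")
  tab <- tab[tab$exposure > 0, , drop = FALSE]
  seg <- as.character(tab$segment)
  if (!first_pulse_distinct) seg[seg == "first_pulse"] <- "later_pulse"
  tab$seg <- factor(seg, levels = intersect(segment_levels, unique(seg)))

  # identifiability: a free log-rate (or covariate effect) needs >= 1
  # event in its stratum
  non_id <- character(0)
  for (L in levels(tab$seg)) {
    if (sum(tab$events[tab$seg == L]) == 0)
      non_id <- c(non_id, paste0("alpha[", L, "]"))
    if (diabetes_effect == "by_segment" &&
        sum(tab$events[tab$seg == L & tab$diabetic == 1]) == 0 &&
        any(tab$diabetic == 1))
      non_id <- c(non_id, paste0("beta[", L, "]"))
  }
  if (length(non_id))
    warning("non-identifiable parameter(s), estimates on the boundary: ",
            paste(non_id, collapse = ", "))

  with_cov <- diabetes_effect == "by_segment" && any(tab$diabetic == 1)
  one_seg <- nlevels(tab$seg) == 1
  fml <- if (one_seg) {
    if (with_cov) events ~ diabetic else events ~ 1
  } else {
    if (with_cov) events ~ 0 + seg + seg:diabetic else events ~ 0 + seg
  }
  fit <- stats::glm(fml, family = stats::poisson(),
                    offset = log(exposure), data = tab)
  cf <- stats::coef(fit)
  if (one_seg) { # name the collapsed design like the general one
    lv <- levels(tab$seg)
    names(cf)[names(cf) == "(Intercept)"] <- paste0("seg", lv)
    names(cf)[names(cf) == "diabetic"] <- paste0("seg", lv, ":diabetic")
  }

  # map glm coefficients onto (alpha_k, beta_k), k = first/later/between
  alpha <- beta <- c(first_pulse = 0, later_pulse = 0, between = 0)
  for (L in segment_levels) {
    L2 <- if (!first_pulse_distinct && L == "first_pulse") "later_pulse" else L
    a <- cf[paste0("seg", L2)]
    alpha[L] <- if (is.na(a)) -Inf else a
    b <- cf[paste0("seg", L2, ":diabetic")]
    beta[L] <- if (length(b) == 0 || is.na(b)) 0 else b
  }
  params <- poisson_params(alpha = pmax(alpha, -745),
                           beta = ifelse(is.finite(beta), beta, 0))

  mm <- stats::model.matrix(fit)
  resid_work <- tab$events - stats::fitted(fit)
  scores <- rowsum(mm * resid_work, group = tab$cell_id)
  colnames(scores) <- names(cf)
  naive_vcov <- stats::vcov(fit)
  dimnames(naive_vcov) <- list(names(cf), names(cf))
  H <- -solve(naive_vcov)
  sand <- sandwich_variance(H, as.matrix(scores))

  # survival-form log-likelihood: sum d*log(rate) - rate*exposure
  ll <- sum(tab$events * log(stats::fitted(fit) / tab$exposure) -
              stats::fitted(fit))
  structure(list(params = params, coef = cf, loglik = ll,
                 naive_vcov = naive_vcov, robust_vcov = sand$R,
                 scores = as.matrix(scores),
                 n_clusters = length(unique(tab$cell_id)),
                 first_pulse_distinct = first_pulse_distinct,
                 diabetes_effect = diabetes_effect,
                 non_identifiable = non_id,
                 converged = fit$converged && length(non_id) == 0,
                 glm = fit, table = tab),
            class = "pexp_fit")
}

#' Wald confidence interval
#'
#' `estimate +/- z * se` on the working scale, optionally
#' back-transformed through `exp` (for rates estimated on the log
#' scale).
#'
#' @param estimate,se Point estimate and standard error (working scale).
#' @param level Confidence level, default 0.95.
#' @param transform `"identity"` or `"exp"`.
#' @return Numeric `c(lower, upper)`.
#' @export
wald_interval <- function(estimate, se, level = 0.95,
                          transform = c("identity", "exp")) {
  transform <- match.arg(transform)
  stopifnot(se >= 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- estimate + c(-1, 1) * z * se
  if (transform == "exp") exp(ci) else ci
}

# linear contrast c'theta on the glm coefficients with robust and naive
# t-tests (df = J - 1; the df convention for cluster-corrected t-tests
# is a documented package choice)
pexp_contrast <- function(fit, contrast) {
  est <- sum(contrast * fit$coef)
  se_r <- sqrt(drop(t(contrast) %*% fit$robust_vcov %*% contrast))
  se_n <- sqrt(drop(t(contrast) %*% fit$naive_vcov %*% contrast))
  df <- fit$n_clusters - 1
  list(estimate = est, se_robust = se_r, se_naive = se_n,
       p_robust = 2 * stats::pt(-abs(est / se_r), df = df),
       p_naive = 2 * stats::pt(-abs(est / se_n), df = df))
}

coef_unit <- function(fit, name) {
  v <- numeric(length(fit$coef)); names(v) <- names(fit$coef)
  if (name %in% names(v)) v[name] <- 1 else return(NULL)
  v
}

#' @export
print.pexp_fit <- function(x, ...) {
  cat("Piecewise-exponential hazard fit (", x$n_clusters,
      " clusters)\n", sep = "")
  cat("log-likelihood:", format(x$loglik), "\n")
  print(summary(x), digits = 3)
  invisible(x)
}

#' Table-style summary of a piecewise-exponential fit
#'
#' One row per reported parameter: baseline rates \eqn{\rho_k}
#' (back-transformed from the log scale) and covariate effects
#' \eqn{\beta_k}. Rate rows carry p-values for the rate-comparison
#' nulls \eqn{\rho_0 = \rho_1} and \eqn{\rho_2 = \rho_1} (linear
#' contrasts on the log scale); effect rows test \eqn{\beta_k = 0}.
#' Cluster-robust (sandwich) and naive p-values are both shown.
#'
#' @param object A `pexp_fit`.
#' @param level Confidence level for the Wald intervals (robust SEs).
#' @param ... Unused.
#' @return Data frame with columns `parameter`, `estimate`, `lower`,
#'   `upper`, `p`, `p_naive`.
#' @export
summary.pexp_fit <- function(object, level = 0.95, ...) {
  segs <- if (object$first_pulse_distinct)
    segment_levels else c("later_pulse", "between")
  kidx <- c(first_pulse = 0, later_pulse = 1, between = 2)
  rows <- list()
  for (L in segs) {
    nm <- paste0("seg", L)
    cv <- coef_unit(object, nm)
    if (is.null(cv)) next
    est <- sum(cv * object$coef)
    se <- sqrt(drop(t(cv) %*% object$robust_vcov %*% cv))
    ci <- wald_interval(est, se, level, transform = "exp")
    ref <- coef_unit(object, "seglater_pulse")
    p <- p_naive <- NA_real_
    if (L != "later_pulse" && !is.null(ref)) {
      ct <- pexp_contrast(object, cv - ref)
      p <- ct$p_robust; p_naive <- ct$p_naive
    }
    rows[[length(rows) + 1]] <-
      data.frame(parameter = paste0("rho", kidx[L]), estimate = exp(est),
                 lower = ci[1], upper = ci[2], p = p, p_naive = p_naive)
  }
  if (object$diabetes_effect == "by_segment") {
    for (L in segs) {
      nm <- paste0("seg", L, ":diabetic")
      cv <- coef_unit(object, nm)
      if (is.null(cv)) next
      est <- sum(cv * object$coef)
      se <- sqrt(drop(t(cv) %*% object$robust_vcov %*% cv))
      ci <- wald_interval(est, se, level)
      ct <- pexp_contrast(object, cv)
      rows[[length(rows) + 1]] <-
        data.frame(parameter = paste0("beta", kidx[L]), estimate = est,
                   lower = ci[1], upper = ci[2], p = ct$p_robust,
                   p_naive = ct$p_naive)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
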