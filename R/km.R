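#' Kaplan-Meier estimate for a covariate stratum
#'
#' Model-free product-limit estimate of the granule survival function
#' (probability of no exocytosis by time t), computed with
#' [survival::survfit()]; granules censored at an event time are
#' counted at risk at that time (censoring-after-events convention).
#' Pointwise confidence bands use the log-minus-log (Greenwood)
#' variance form.
#'
#' @param gd A [granule_data()].
#' @param stratum Covariate value (0 or 1) selecting the stratum, or
#'   `NULL` for the pooled data.
#' @param level Confidence level of the pointwise bands.
#' @return Object of class `km_estimate`: a data frame with columns
#'   `time`, `n_risk`, `n_event`, `survival`, `lower`, `upper`.
#' @export
kaplan_meier <- function(gd, stratum = NULL, level = 0.95) {
  stopifnot(inherits(gd, "granule_data"))
  d <- gd$data
  if (!is.null(stratum)) d <- d[d$diabetic == stratum, , drop = FALSE]
  if (nrow(d) == 0) stop("empty stratum")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                          conf.type = "log-log", conf.int = level)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, survival = sf$surv,
                    lower = ifelse(is.na(sf$lower), 0, sf$lower),
                    upper = ifelse(is.na(sf$upper), 1, sf$upper))
  structure(out, stratum = stratum, n = nrow(d),
            class = c("km_estimate", "data.frame"))
}

# right-continuous step evaluation of a KM curve: S(t), S(0) = 1
km_survival_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$survival)[idx + 1]
}

#' Model and Kaplan-Meier incidence curves on a common grid
#'
#' Assembles, per covariate stratum, the nonparametric cumulative
#' incidence (with its confidence band) and the frailty-model marginal
#' incidence together with its IRP and non-IRP components -- the data
#' behind a model-vs-data overlay figure.
#'
#' @param params A [frailty_params()] (e.g. from a fitted model).
#' @param gd A [granule_data()].
#' @param grid Time grid; default 0 to `observation_end` by 0.1 s.
#' @return Data frame with columns `time`, `covariate`, `km`,
#'   `km_lower`, `km_upper`, `marginal`, `irp`, `non_irp` (all on the
#'   cumulative-incidence scale).
#' @export
curves_table <- function(params, gd,
                         grid = seq(0, gd$protocol$observation_end,
                                    by = 0.1)) {
  stopifnot(inherits(params, "frailty_params"))
  out <- lapply(sort(unique(gd$data$diabetic)), function(x) {
    km <- kaplan_meier(gd, stratum = x)
    comp <- incidence_components(grid, x, params, gd$protocol)
    ups <- stats::stepfun(km$time, c(1, km$upper), right = FALSE)
    los <- stats::stepfun(km$time, c(1, km$lower), right = FALSE)
    data.frame(time = grid, covariate = x,
               km = 1 - km_survival_at(km, grid),
               km_lower = 1 - ups(grid), km_upper = 1 - los(grid),
               marginal = comp$marginal$value, irp = comp$irp$value,
               non_irp = comp$non_irp$value)
  })
  do.call(rbind, out)
}
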