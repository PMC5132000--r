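test_that("episode splitting partitions follow-up by segment class", {
  suppressWarnings({
    gd <- tiny_gd(c(100, 15), c(0, 1))
  })
  tab <- episode_split(gd)
  g1 <- tab[tab$granule_id == "g1", ]
  expect_equal(g1$exposure[match(c("first_pulse", "later_pulse", "between"),
                                 g1$segment)], c(1, 9, 90))
  expect_equal(sum(g1$events), 0)
  g2 <- tab[tab$granule_id == "g2", ]
  expect_equal(g2$exposure[match(c("first_pulse", "later_pulse", "between"),
                                 g2$segment)], c(1, 1, 13))
  expect_equal(g2$events[g2$segment == "between"], 1)
  expect_equal(sum(g2$events), 1)
})

test_that("exposures are conserved for every granule", {
  gd <- small_sim(seed = 5, gpc = 60, v = 0.5)
  tab <- episode_split(gd)
  key <- function(d) paste(d$cell_id, d$granule_id)
  tot <- tapply(tab$exposure, key(tab), sum)
  expect_equal(as.numeric(tot[key(gd$data)]), gd$data$time,
               tolerance = 1e-12)
  expect_equal(as.numeric(tapply(tab$events, key(tab), sum)[key(gd$data)]),
               gd$data$event)
})

test_that("single-stratum rate MLE is events over exposure", {
  tab <- data.frame(cell_id = rep("c1", 20), granule_id = paste0("g", 1:20),
                    segment = factor("later_pulse", levels =
                      c("first_pulse", "later_pulse", "between")),
                    diabetic = 0, exposure = 5, events = rep(c(1, 0), c(5, 15)))
  fit <- fit_piecewise_exponential(tab, diabetes_effect = "none")
  expect_equal(exp(fit$params$alpha[2]), 5 / 100, tolerance = 1e-8)
})

test_that("Poisson-table likelihood equals the survival-form likelihood", {
  gd <- small_sim(seed = 13, gpc = 80, v = 0.5)
  fit <- suppressWarnings(fit_piecewise_exponential(gd))
  expect_lt(abs(fit$loglik - survival_loglik(fit$params, gd)), 1e-10)
  # and the fitted likelihood is at least the likelihood at the truth
  expect_gte(fit$loglik, survival_loglik(
    poisson_params(alpha = log(c(0.00117 * 499.5 * 0.026 + 0.00117,
                                 0.00117, 0.00014)),
                   beta = c(0, 0, 1.43)), gd) - 1e-8)
})

test_that("refining segments does not change the fit", {
  gd <- small_sim(seed = 17, gpc = 60, v = 0)
  tab <- episode_split(gd)
  # split every between-spell into two rows of half the exposure
  btw <- tab[tab$segment == "between", ]
  half1 <- transform(btw, exposure = exposure / 2, events = 0)
  half2 <- transform(btw, exposure = exposure / 2)
  tab2 <- rbind(tab[tab$segment != "between", ], half1, half2)
  f1 <- fit_piecewise_exponential(tab)
  f2 <- fit_piecewise_exponential(tab2)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("piecewise rates are recovered from simulated data", {
  # no frailty, no heterogeneity: a plain piecewise-exponential law
  truth <- frailty_params(alpha1 = log(0.0013), alpha2 = log(0.0003),
                          beta2 = 0.98, eta = 1, pi0 = 0)
  gd <- small_sim(seed = 23, n_h = 60, n_d = 60, gpc = 200, truth = truth,
                  v = 0)
  fit <- fit_piecewise_exponential(gd, first_pulse_distinct = FALSE)
  se <- sqrt(diag(fit$naive_vcov))
  est <- fit$coef
  expect_lt(abs(est[["seglater_pulse"]] - log(0.0013)),
            3 * se[["seglater_pulse"]])
  expect_lt(abs(est[["segbetween"]] - log(0.0003)),
            3 * se[["segbetween"]])
  expect_lt(abs(est[["segbetween:diabetic"]] - 0.98),
            3 * se[["segbetween:diabetic"]])
})

test_that("non-identifiable strata are flagged, not silently dropped", {
  # diabetic granules without a single event between pulses
  df <- data.frame(cell_id = rep(c("h1", "d1"), each = 30),
                   granule_id = paste0("g", 1:60),
                   time = rep(100, 60), event = 0,
                   diabetic = rep(c(0, 1), each = 30))
  df$event[c(1, 5, 31)] <- 1
  df$time[c(1, 5)] <- c(0.5, 55)   # healthy events
  df$time[31] <- 0.2               # diabetic event in first pulse only
  gd <- granule_data(df)
  expect_warning(fit_piecewise_exponential(gd), "non-identifiable")
})

test_that("wald intervals behave on both scales", {
  expect_equal(wald_interval(0, 1), c(-1.959964, 1.959964),
               tolerance = 1e-6)
  expect_equal(wald_interval(2, 0), c(2, 2))
  ci <- wald_interval(log(0.0013), 0.4, transform = "exp")
  expect_true(all(ci > 0))
  expect_true(ci[1] < 0.0013 && 0.0013 < ci[2])
})

test_that("cluster sandwich matches the reference implementation and behaves under clustering", {
  skip_if_not_installed("sandwich")
  gd <- small_sim(seed = 29, gpc = 80, v = 0.5)
  fit <- fit_piecewise_exponential(gd)
  ref <- sandwich::vcovCL(fit$glm, cluster = fit$table$cell_id,
                          type = "HC0", cadjust = FALSE)
  expect_equal(unname(fit$robust_vcov), unname(ref), tolerance = 1e-6)

  # independent clusters: robust and naive standard errors agree
  truth <- frailty_params(alpha1 = log(0.002), alpha2 = log(3e-4),
                          beta2 = 0.5, eta = 1, pi0 = 0)
  gd0 <- small_sim(seed = 37, n_h = 120, n_d = 120, gpc = 100,
                   truth = truth, v = 0)
  f0 <- fit_piecewise_exponential(gd0, first_pulse_distinct = FALSE)
  ratio0 <- sqrt(diag(f0$robust_vcov)) / sqrt(diag(f0$naive_vcov))
  expect_true(all(ratio0 > 0.8 & ratio0 < 1.2))

  # shared cell factors: robust SEs exceed naive SEs
  gdh <- small_sim(seed = 37, n_h = 120, n_d = 120, gpc = 100,
                   truth = truth, v = 0.5)
  fh <- fit_piecewise_exponential(gdh, first_pulse_distinct = FALSE)
  ratioh <- sqrt(diag(fh$robust_vcov)) / sqrt(diag(fh$naive_vcov))
  expect_gt(mean(ratioh), 1.15)
})
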