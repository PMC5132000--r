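# Builders shared across the suite. All fixtures are constructed in
# code; nothing is read from disk.

# a tiny hand-specified dataset: one row per granule
tiny_gd <- function(times, events, X = 0, cell = "c1",
                    protocol = stim_protocol()) {
  granule_data(data.frame(
    cell_id = rep_len(cell, length(times)),
    granule_id = paste0("g", seq_along(times)),
    time = times, event = events,
    diabetic = rep_len(X, length(times))), protocol)
}

# default generating mechanism used widely in tests: the frailty-model
# parameter values of the study's frailty report, as simulation truth
table2_truth <- function() frailty_params(
  alpha1 = log(0.00117), alpha2 = log(0.00014),
  beta2 = 1.43, eta = 499.5, pi0 = 0.026, pi1 = 0.010)

# small clustered simulation (fast default for unit tests)
small_sim <- function(seed, n_h = 6, n_d = 5, gpc = 40,
                      truth = table2_truth(), v = 0) {
  simulate_dataset(
    simulation_design(n_cells_healthy = n_h, n_cells_diabetic = n_d,
                      granules_per_cell = gpc, truth = truth,
                      cell_heterogeneity_variance = v),
    seed = seed)
}

# random plausible working-scale parameter vector
rand_theta <- function() {
  c(alpha1 = stats::runif(1, log(5e-4), log(5e-3)),
    alpha2 = stats::runif(1, log(5e-5), log(5e-4)),
    beta2 = stats::runif(1, -1, 2),
    log_eta = stats::runif(1, log(5), log(800)),
    pi0 = stats::runif(1, 0.005, 0.2),
    pi1 = stats::runif(1, 0.005, 0.2))
}

# quadratic (Gaussian) log-likelihood factory for the adjustment tests:
# l(theta) = -0.5 * sum((theta - mu)^2 / sigma^2)
quad_loglik <- function(mu, sigma) {
  force(mu); force(sigma)
  function(theta) -0.5 * sum((theta - mu)^2 / sigma^2)
}
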