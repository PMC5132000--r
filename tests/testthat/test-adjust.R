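test_that("per-cluster scores sum to zero at the MLE and match analytic ones", {
  gd <- small_sim(seed = 73, gpc = 50, v = 0.5)
  fit <- fit_frailty(gd, starts = list(as_working_theta(table2_truth())))
  U_num <- score_by_cluster(
    function(th) loglik_independence(th, gd, by_cluster = TRUE),
    fit$theta_hat)
  U_ana <- cluster_scores(fit)
  expect_equal(unname(U_num), unname(U_ana[rownames(U_num), ]),
               tolerance = 1e-5)
  total <- colSums(U_ana)
  expect_lt(sqrt(sum(total^2)), 1e-3)
})

test_that("with a single cluster the score equals the full gradient", {
  skip_if_not_installed("numDeriv")
  gd <- small_sim(seed = 79, n_h = 1, n_d = 0, gpc = 80)
  th <- as_working_theta(table2_truth())
  U <- score_by_cluster(
    function(x) loglik_independence(x, gd, by_cluster = TRUE), th)
  expect_equal(nrow(U), 1)
  g <- numDeriv::grad(function(x) loglik_independence(x, gd), th)
  expect_equal(as.numeric(U[1, ]), g, tolerance = 1e-5)
})

test_that("scores of a one-parameter exponential model match the hand formula", {
  # units observed on (0, tmax] with constant rate rho, clusters of 1:
  # l_j = d_j log(rho) - rho * t_j, so U_j = d_j / rho - t_j
  set.seed(83)
  rho <- 0.3
  t <- round(runif(8, 0.5, 4), 3)
  d <- rbinom(8, 1, 0.7)
  ll_by_unit <- function(theta)
    setNames(d * log(theta[1]) - theta[1] * t, paste0("u", 1:8))
  U <- score_by_cluster(ll_by_unit, rho)
  expect_equal(as.numeric(U), d / rho - t, tolerance = 1e-8)
})

test_that("sandwich algebra handles degenerate and identity cases", {
  H <- matrix(c(-4, 1, 1, -2), 2)
  zero_scores <- matrix(0, nrow = 6, ncol = 2)
  expect_equal(sandwich_variance(H, zero_scores)$R, 0 * H)
  # information identity V = -H in one dimension: robust = naive
  H1 <- matrix(-5, 1, 1)
  scores1 <- matrix(c(1, -2, 0), ncol = 1)  # crossprod = 5 = -H
  sw <- sandwich_variance(H1, scores1)
  expect_equal(sw$R, -solve(H1))
  expect_error(sandwich_variance(matrix(0, 2, 2), zero_scores), "singular")
})

test_that("the adjusted likelihood has the prescribed optimum and curvature", {
  gd <- small_sim(seed = 89, n_h = 20, n_d = 20, gpc = 100, v = 0.5)
  fit <- fit_frailty(gd, starts = list(as_working_theta(table2_truth())))
  expect_false(any(fit$boundary)) # interior optimum: adjustment well posed
  adj <- adjusted_inference(fit)
  # same maximum value and location
  expect_equal(adj$loglik_A(fit$theta_hat), fit$loglik, tolerance = 1e-12)
  # curvature at the optimum is minus the inverse sandwich variance;
  # steps scale with the robust SE per coordinate (wide steps through
  # the adjustment transform can leave the likelihood's domain)
  H_A <- exofrailty:::fd_hessian(adj$loglik_A, fit$theta_hat,
                                 h = 0.1 * sqrt(diag(adj$R)))
  target <- -solve(adj$R)
  expect_lt(norm(H_A - target, "F") / norm(target, "F"), 1e-4)
  # identity adjustment: C = I and l_A == l_I everywhere
  nai <- adjusted_inference(fit, adjust = FALSE)
  expect_equal(unname(nai$C), diag(6), tolerance = 1e-8)
  th <- fit$theta_hat * 1.01
  expect_equal(nai$loglik_A(th), loglik_independence(th, gd),
               tolerance = 1e-8)
})

test_that("adjustment construction rejects non-positive-definite input", {
  gd <- small_sim(seed = 97, gpc = 40, v = 0)
  fit <- fit_frailty(gd, starts = list(as_working_theta(table2_truth())))
  Hbad <- fit$hessian
  Hbad[1, 1] <- abs(Hbad[1, 1]) # positive curvature: not a maximum
  expect_error(build_adjustment(Hbad, solve(-fit$hessian),
                                function(th) loglik_independence(th, gd),
                                fit$theta_hat),
               "not positive definite")
})

test_that("likelihood-ratio p-values use the chi-square and boundary-mixture references", {
  # quadratic likelihood: Lambda for the null theta_k = 0 is (mu_k/sigma_k)^2
  sigma <- c(1, 2, 0.5)
  make_adj <- function(mu) {
    H <- diag(-1 / sigma^2)
    build_adjustment(H, solve(-H), quad_loglik(mu, sigma), theta_hat = mu)
  }
  adj <- make_adj(c(sqrt(3.841459), 1, -2))
  lr <- lrt_adjusted(adj, param = 1, null_value = 0)
  expect_equal(lr$statistic, 3.841459, tolerance = 1e-4)
  expect_equal(lr$p_value, 0.05, tolerance = 1e-3)
  adjb <- make_adj(c(sqrt(2.705543), 1, -2))
  lrb <- lrt_adjusted(adjb, param = 1, null_value = 0, boundary = TRUE)
  expect_equal(lrb$statistic, 2.705543, tolerance = 1e-4)
  expect_equal(lrb$p_value, 0.05, tolerance = 1e-3)
  # a null already satisfied at the optimum: Lambda = 0, p = 1 in both
  adj0 <- make_adj(c(0, 1, -2))
  expect_equal(lrt_adjusted(adj0, param = 1, null_value = 0)$p_value, 1)
  expect_equal(lrt_adjusted(adj0, param = 1, null_value = 0,
                            boundary = TRUE)$p_value, 1)
  # equality constraint: Lambda = (mu_i - mu_j)^2 / (sigma_i^2 + sigma_j^2)
  adje <- make_adj(c(2, 1, -2))
  lre <- lrt_adjusted(adje, equal = c(1, 2))
  expect_equal(lre$statistic, (2 - 1)^2 / (1 + 4), tolerance = 1e-4)
})

test_that("profile intervals match the closed Gaussian form and nest by level", {
  mu <- c(0.7, -1.2, 3)
  sigma <- c(0.5, 2, 1)
  H <- diag(-1 / sigma^2)
  adj <- build_adjustment(H, solve(-H), quad_loglik(mu, sigma),
                          theta_hat = mu)
  for (k in 1:3) {
    ci <- profile_ci(adj, k, level = 0.95)
    expect_equal(as.numeric(ci),
                 mu[k] + c(-1, 1) * 1.959964 * sigma[k], tolerance = 1e-4)
    expect_true(ci[1] < mu[k] && mu[k] < ci[2])
  }
  ci90 <- profile_ci(adj, 1, level = 0.90)
  ci95 <- profile_ci(adj, 1, level = 0.95)
  expect_gt(ci90[1], ci95[1])
  expect_lt(ci90[2], ci95[2])
})

test_that("profile intervals on a fitted frailty model bracket the estimates", {
  gd <- small_sim(seed = 101, n_h = 12, n_d = 10, gpc = 80, v = 0.5)
  fit <- fit_frailty(gd, starts = list(as_working_theta(table2_truth())))
  adj <- adjusted_inference(fit)
  for (nm in c("alpha1", "log_eta", "pi0")) {
    ci <- suppressWarnings(profile_ci(adj, nm))
    expect_true(ci[1] <= fit$theta_hat[nm] &&
                  fit$theta_hat[nm] <= ci[2])
  }
})
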