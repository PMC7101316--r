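test_that("M-step recovers the generating logistic parameters from exact PIPs", {
  a <- rep(c(1, 0), c(100, 900))
  pip <- prior_pi(-2, 1, a)
  ms <- m_step(pip, a)
  expect_equal(ms$tau, c(-2, 1), tolerance = 1e-6)
  expect_true(ms$converged)
  # constant pip carries no membership information
  ms2 <- m_step(rep(0.3, 1000), a)
  expect_equal(ms2$tau[2], 0, tolerance = 1e-6)
  expect_equal(ms2$tau[1], qlogis(0.3), tolerance = 1e-6)
  ms3 <- m_step(rep(0.5, 100), rep(c(1, 0), 50))
  expect_equal(ms3$tau, c(0, 0), tolerance = 1e-6)
  # degenerate membership is rejected
  expect_error(m_step(pip, rep(1, 1000)), "zeros and ones")
})

test_that("perfect separation clamps tau and flags non-convergence", {
  a <- rep(c(1, 0), each = 50)
  ms <- m_step(as.numeric(a), a)
  expect_false(ms$converged)
  expect_true(all(abs(ms$tau) <= 25 + 1e-9))
})

test_that("Gibbs stationary inclusion probabilities match the closed form", {
  set.seed(21)
  p <- 50
  z <- rnorm(p, 0, 2)
  a <- rbinom(p, 1, 0.3)
  tau <- c(-1.5, 0.7)
  # sigma2 held fixed: genes are a-posteriori independent and the
  # responsibility is exact
  es <- e_step(z, a = a, tau = tau, sigma2 = 9,
               config = mcmc_config(40000, 1000),
               update_sigma2 = FALSE)
  r <- spike_slab_responsibility(z, prior_pi(tau[1], tau[2], a), 9)
  mc_se <- sqrt(r * (1 - r) / 39000)
  dev <- abs(es$pip - r) / pmax(mc_se, 1e-12)
  expect_lt(max(dev), 4)
  expect_lt(mean(dev), 1.5)
})

test_that("score-sample covariance matches the independence closed form", {
  set.seed(22)
  p <- 100
  z <- rnorm(p, 0, 2)
  a <- rbinom(p, 1, 0.3)
  tau <- c(-1.5, 0.7)
  es <- e_step(z, a = a, tau = tau, sigma2 = 9,
               config = mcmc_config(20000, 500),
               update_sigma2 = FALSE)
  r <- spike_slab_responsibility(z, prior_pi(tau[1], tau[2], a), 9)
  w <- r * (1 - r)
  I_ind <- rbind(c(sum(w), sum(w * a)), c(sum(w * a), sum(w * a)))
  I_mis <- cov(es$scores)
  expect_equal(I_mis, I_ind, tolerance = 0.05)
})

test_that("slab variance falls back to its prior when no gene is included", {
  set.seed(23)
  es <- e_step(rnorm(200), a = NULL, tau = c(-30, 0), sigma2 = 10,
               config = mcmc_config(20000, 200), update_sigma2 = TRUE)
  expect_lt(max(es$pip), 1e-3)
  expect_equal(es$sigma2, 10, tolerance = 0.5)  # InvGamma(3, 20) mean
})

test_that("Louis test: degenerate posteriors reduce to the complete-data Wald", {
  a <- rep(c(1, 0), c(30, 70))
  tau <- c(-1, 0.5)
  scores <- matrix(0, 50, 2)  # zero-variance score samples
  lw <- louis_wald_test(scores, a, tau)
  pi <- prior_pi(tau[1], tau[2], a)
  w <- pi * (1 - pi)
  I_com <- rbind(c(sum(w), sum(w * a)), c(sum(w * a), sum(w * a)))
  expect_equal(lw$cov_tau, solve(I_com), tolerance = 1e-8)
  expect_equal(lw$p_value,
               pchisq(tau[2]^2 / solve(I_com)[2, 2], 1, lower.tail = FALSE))
  # tau1 = 0 gives a Wald statistic of zero and p = 1
  lw0 <- louis_wald_test(scores, a, c(-1, 0))
  expect_equal(lw0$statistic, 0)
  expect_equal(lw0$p_value, 1)
})

test_that("Louis-corrected variance is at least the complete-data variance", {
  dat <- sim_model_data(2000, tau1 = 1, seed = 31)
  fit <- fit_gene_set(dat$stats$z, dat$stats$se, dat$truth$a,
                      config = quick_config(seed = 31))
  lw <- louis_wald_test(fit$score_samples, dat$truth$a,
                        unname(fit$tau_hat))
  expect_gte(lw$cov_tau[2, 2], solve(lw$I_com)[2, 2] - 1e-10)
})

test_that("EM increases the observed-data log-likelihood (up to MC noise)", {
  dat <- sim_model_data(2000, tau1 = 1, seed = 9)
  fit <- fit_gene_set(dat$stats$z, dat$stats$se, dat$truth$a,
                      config = mcmc_config(500, 100, seed = 9,
                                           em_max_iter = 15))
  expect_true(all(diff(fit$loglik_trace) > -0.2))
  expect_gt(fit$loglik_trace[length(fit$loglik_trace)],
            fit$loglik_trace[1])
})

test_that("fit_gene_set is bitwise reproducible under a fixed seed", {
  dat <- sim_model_data(500, tau1 = 1, seed = 12)
  f1 <- fit_gene_set(dat$stats$z, dat$stats$se, dat$truth$a,
                     config = quick_config(seed = 77))
  f2 <- fit_gene_set(dat$stats$z, dat$stats$se, dat$truth$a,
                     config = quick_config(seed = 77))
  expect_identical(f1$pip, f2$pip)
  expect_identical(f1$tau_hat, f2$tau_hat)
  expect_identical(f1$p_value, f2$p_value)
})

test_that("degenerate designs error; non-convergence is a flag, not an error", {
  z <- rnorm(10)
  expect_error(fit_gene_set(z, a = rep(1, 10)), "contrast")
  expect_error(fit_gene_set(z, a = rep(0, 10)), "empty")
  expect_error(fit_gene_set(z[1], a = NULL), "at least 2")
  # a one-iteration EM cannot converge: must return with converged = FALSE
  dat <- sim_model_data(300, tau1 = 1, seed = 5)
  fit <- fit_gene_set(dat$stats$z, dat$stats$se, dat$truth$a,
                      config = mcmc_config(200, 50, seed = 5,
                                           em_max_iter = 1))
  expect_s3_class(fit, "enrichment_result")
  expect_false(fit$converged)
})

test_that("scaled and unscaled variants agree when all standard errors are 1", {
  dat <- sim_model_data(500, tau1 = 1, seed = 13)
  fs <- fit_gene_set(dat$stats$z, rep(1, 500), dat$truth$a,
                     config = quick_config(seed = 5), variant = "scaled")
  fu <- fit_gene_set(dat$stats$z, rep(1, 500), dat$truth$a,
                     config = quick_config(seed = 5), variant = "unscaled")
  # with se = 1 the two parameterizations are the same model
  expect_equal(fu$tau_hat, fs$tau_hat, tolerance = 0.15)
  expect_gt(cor(fs$pip, fu$pip), 0.99)
})

test_that("frozen-tau fits skip EM and honour the fixed parameters", {
  dat <- sim_model_data(500, tau1 = 0, seed = 14)
  fit <- fit_gene_set(dat$stats$z, dat$stats$se, dat$truth$a,
                      config = quick_config(seed = 3),
                      tau_fixed = c(-2, 0), fix_sigma2 = 9)
  expect_equal(unname(fit$tau_hat), c(-2, 0))
  expect_equal(fit$sigma_beta2_hat, 9)
  expect_equal(fit$n_em_iter, 0L)
})
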