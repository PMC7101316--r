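test_that("truth assignment hits the benchmark DE fractions", {
  set.seed(61)
  t1 <- assign_truth(20000, 0.1, -2, 0)
  expect_lt(abs(mean(t1$gamma_true) - 0.119), 0.01)
  expect_equal(sum(t1$a), 2000)
  set.seed(62)
  t2 <- assign_truth(20000, 0.01, -3, 0)
  expect_lt(abs(mean(t2$gamma_true) - 0.047), 0.006)
  # no signal when the effect sd is zero
  set.seed(63)
  t3 <- assign_truth(1000, 0.1, -2, 0, effect_sd = 0)
  expect_true(all(t3$fc == 1))
  # set members are enriched for DE when tau1 > 0
  set.seed(64)
  t4 <- assign_truth(20000, 0.1, -2, 1)
  expect_gt(mean(t4$gamma_true[t4$a == 1]), mean(t4$gamma_true[t4$a == 0]))
  expect_equal(t4$fc, exp(t4$beta_true))
  expect_true(all(t4$beta_true[t4$gamma_true == 0] == 0))
})

test_that("ZTNB moment estimation recovers generating parameters", {
  lam_hat <- phi_hat <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    N <- runif(500, 5000, 20000)        # means 5-20: visible truncation
    y <- rnbinom(500, mu = 0.001 * N, size = 2)
    est <- ztnb_mom_estimate(matrix(y, 1), N)
    lam_hat[s] <- est$lambda
    phi_hat[s] <- est$phi
  }
  expect_lt(abs(mean(lam_hat) - 0.001), 0.15 * 0.001)
  expect_lt(abs(mean(phi_hat) - 2), 0.15 * 2)
  # genes with fewer than 3 nonzero counts are excluded
  est <- ztnb_mom_estimate(rbind(c(5, 0, 0, 0), c(3, 2, 4, 1)),
                           rep(1000, 4))
  expect_true(est$excluded[1])
  expect_false(est$excluded[2])
  # large equal counts: negligible truncation, near-Poisson dispersion
  est2 <- ztnb_mom_estimate(matrix(rep(500, 100), 1), rep(1e6, 100))
  expect_lt(abs(est2$lambda - 5e-4), 1e-5)
  expect_gt(est2$phi, 100)
})

test_that("dropout model recovers a known logistic surface", {
  set.seed(3)
  p <- 600; n <- 80
  lambda <- rlnorm(p, log(1e-4), 1)
  N <- rlnorm(n, log(6e5), 0.2)
  counts <- matrix(rnbinom(p * n, mu = outer(lambda, N), size = 3), p)
  # zeros generated from a known logistic surface in (A_j, log N_i)
  A <- log2(rowSums(counts) / sum(N) * 1e6 + 0.5)
  pz <- plogis(outer(1.5 - 0.35 * A, -0.5 * (log(N) - log(1e6)), `+`))
  counts[matrix(runif(p * n), p) < pz] <- 0
  fit <- fit_dropout_model(counts, N, A = A)
  pred <- predict_dropout(fit, lambda, N, A = A)
  expect_lt(sqrt(mean((pred - pz)^2)), 0.05)
  # recovered surface decreases with expression, like the generator
  ord <- order(A)
  expect_lt(mean(pred[ord[501:600], ]), mean(pred[ord[1:100], ]))
  # the default covariate path (abundance from the zeroed counts) stays close
  fit2 <- fit_dropout_model(counts, N)
  pred2 <- predict_dropout(fit2, lambda, N)
  expect_lt(sqrt(mean((pred2 - pz)^2)), 0.1)
  # data with no zeros: predicted dropout collapses to (clamped) zero
  dense <- matrix(rpois(100 * 60, 50) + 1, 100)
  fit0 <- fit_dropout_model(dense, rep(5e3, 60))
  expect_lt(max(predict_dropout(fit0, rep(1e-2, 5), rep(5e3, 3))), 0.05)
  expect_error(fit_dropout_model(matrix(1, 10, 10)), "50 genes")
})

test_that("simulated counts reproduce the generating moments", {
  set.seed(65)
  p <- 300
  params <- data.frame(lambda = rep(2e-4, p), phi = rep(1e6, p))
  truth <- assign_truth(p, 0.1, -2, 0, effect_sd = 1)
  N <- rep(5e5, 300)  # many cells so gene means are tight
  sim <- simulate_counts(params, dropout = NULL, truth,
                         group_sizes = c(150, 150), depths = N)
  means <- rowMeans(sim$counts[, sim$labels == 1])
  expected <- params$lambda * truth$fc * 5e5
  expect_lt(max(abs(means / expected - 1)), 0.05)
  expect_equal(rowMeans(sim$counts[, sim$labels == 2]) / (2e-4 * 5e5),
               rep(1, p), tolerance = 0.05)
})

test_that("dropout only adds zeros beyond the count model", {
  set.seed(66)
  p <- 500
  params <- data.frame(lambda = rlnorm(p, log(1e-5), 1),
                       phi = rep(2, p))
  truth <- assign_truth(p, 0.1, -2, 0, effect_sd = 0)
  N <- rlnorm(100, log(5e5), 0.1)
  base <- simulate_counts(params, dropout = NULL, truth, c(50, 50),
                          depths = N)
  set.seed(66)
  with_dz <- simulate_counts(params, dropout_surface(), truth, c(50, 50),
                             depths = N)
  expect_gt(mean(with_dz$counts == 0), mean(base$counts == 0))
  # per-gene observed zero fraction dominates the NB-implied fraction
  nb_zero <- rowMeans(sapply(N, function(d)
    dnbinom(0, mu = params$lambda * d, size = params$phi)))
  obs_zero <- rowMeans(with_dz$counts == 0)
  expect_gt(mean(obs_zero - nb_zero), 0)
})

test_that("the NB Wald test is calibrated on its own model and signs effects", {
  set.seed(67)
  p <- 2000
  params <- data.frame(lambda = rlnorm(p, log(1e-4), 1),
                       phi = pmax(rgamma(p, 2, scale = 1), 0.2))
  truth <- assign_truth(p, 0.1, -2, 0, effect_sd = 0)  # fc = 1: full null
  N <- rlnorm(120, log(8e5), 0.2)
  sim <- simulate_counts(params, dropout = NULL, truth, c(60, 60),
                         depths = N)
  st <- internal_de_test(sim$counts, sim$labels, depths = N)
  ok <- st$flag != 2L & is.finite(st$p)
  lam <- genomic_control_lambda(st$p[ok])
  expect_gt(lam, 0.85)
  expect_lt(lam, 1.2)
  expect_gt(stats::ks.test(st$p[ok], "punif")$p.value, 0.001)
  # under dropout the test stays conservative, never anticonservative
  set.seed(68)
  simd <- simulate_counts(params, dropout_surface(), truth, c(60, 60),
                          depths = N)
  std <- internal_de_test(simd$counts, simd$labels)
  okd <- std$flag != 2L & is.finite(std$p)
  expect_lt(genomic_control_lambda(std$p[okd]), 1.2)
  # a strong induced fold change is detected with the right sign
  truth2 <- truth
  truth2$fc[1] <- exp(3)
  set.seed(69)
  sim2 <- simulate_counts(params, dropout = NULL, truth2, c(60, 60),
                          depths = N)
  st2 <- internal_de_test(sim2$counts, sim2$labels, depths = N)
  expect_gt(st2$z[1], 5)
  expect_equal(st2$beta_hat[1], 3, tolerance = 0.5)
  # an all-zero gene is excluded
  cz <- sim2$counts
  cz[2, ] <- 0
  st3 <- internal_de_test(cz, sim2$labels, depths = N)
  expect_equal(st3$flag[2], 2L)
  expect_true(is.na(st3$z[2]))
})

test_that("model-simulated z-scores have the stated mixture moments", {
  set.seed(70)
  truth <- assign_truth(10000, 0.1, -2, 0)
  st0 <- simulate_summary_stats(truth, se = 1, sigma_beta2 = 0)
  expect_gt(stats::ks.test(st0$z, "pnorm")$p.value, 0.01)
  set.seed(71)
  truth2 <- assign_truth(10000, 0.1, -1, 0)
  st <- simulate_summary_stats(truth2, se = 1, sigma_beta2 = 9)
  expect_equal(var(st$z[truth2$gamma_true == 1]), 10, tolerance = 0.5)
  expect_equal(var(st$z[truth2$gamma_true == 0]), 1, tolerance = 0.05)
  # gamma = 0 everywhere gives a standard normal sample
  set.seed(72)
  truth3 <- assign_truth(10000, 0.1, -30, 0)
  st3 <- simulate_summary_stats(truth3, se = 1, sigma_beta2 = 9)
  expect_gt(stats::ks.test(st3$z, "pnorm")$p.value, 0.01)
  # beta_hat = z * se
  st4 <- simulate_summary_stats(truth3[1:10, ], se = 2, sigma_beta2 = 9)
  expect_equal(st4$beta_hat, st4$z * 2)
})

test_that("simulation round-trips through plain-text files", {
  set.seed(73)
  rf <- reference_free_params(80, 20)
  truth <- assign_truth(80, 0.1, -2, 0)
  sim <- simulate_counts(rf$params, rf$dropout, truth, c(12, 8),
                         depths = rf$depths)
  dir <- tempfile()
  write_simulation(sim, dir)
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  expect_equal(unname(counts), unname(sim$counts))
  tr <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(tr$gamma, sim$truth$gamma_true)
})
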