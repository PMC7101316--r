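#' MCMC and EM configuration for gene-set fitting
#'
#' @param n_sweeps Gibbs sweeps per E-step (default 1000).
#' @param burn_in discarded sweeps per E-step (default 500; must be smaller
#'   than `n_sweeps`).
#' @param seed optional integer seed; when set, [fit_gene_set()] is bitwise
#'   reproducible.
#' @param em_max_iter maximum EM iterations (default 50).
#' @param em_tol EM convergence tolerance on `max |delta tau|` (default
#'   1e-3). With soft posterior inclusion probabilities the Monte Carlo
#'   noise in the M-step update can exceed this tolerance, in which case the
#'   fit runs to `em_max_iter` and reports `converged = FALSE`.
#' @param warmup_sweeps,warmup_burn_in optional shorter chain used for the
#'   intermediate E-steps inside the EM loop (Monte Carlo EM with a lighter
#'   warmup chain); the final E-step that produces PIPs and score samples
#'   always uses `n_sweeps`/`burn_in`. Defaults to the full lengths.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_sweeps = 1000L, burn_in = 500L, seed = NULL,
                        em_max_iter = 50L, em_tol = 1e-3,
                        warmup_sweeps = NULL, warmup_burn_in = NULL) {
  stopifnot(n_sweeps >= 1, burn_in >= 1, burn_in < n_sweeps,
            em_max_iter >= 1, em_tol > 0)
  if (is.null(warmup_sweeps)) warmup_sweeps <- n_sweeps
  if (is.null(warmup_burn_in)) warmup_burn_in <- burn_in
  stopifnot(warmup_burn_in < warmup_sweeps)
  structure(list(n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in), seed = seed,
                 em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 warmup_sweeps = as.integer(warmup_sweeps),
                 warmup_burn_in = as.integer(warmup_burn_in)),
            class = "mcmc_config")
}

.cvec_for_variant <- function(variant, se, p) {
  switch(variant,
         scaled = rep(1, p),
         unscaled = {
           if (is.null(se)) stop("the unscaled variant requires standard errors")
           1 / se^2
         },
         stop("unknown model variant: ", variant))
}

#' Gibbs-sampling E-step
#'
#' Runs the systematic-scan Gibbs sampler over the latent DE indicators,
#' effect sizes, and (optionally) the slab variance, with the logistic prior
#' parameters held fixed. Returns post-burn-in averages of the indicators
#' (the posterior inclusion probabilities), the posterior mean slab variance,
#' and the per-sweep complete-data score vectors
#' `S(tau) = sum_j x_j (gamma_j - pi_j)`, `x_j = (1, a_j)`, used by the
#' Louis correction.
#'
#' @param z numeric vector of z-scores.
#' @param se standard errors (needed for `variant = "unscaled"` only).
#' @param a binary membership vector, or `NULL` for the intercept-only model.
#' @param tau numeric `(tau0, tau1)`; `tau[2]` is ignored when `a` is `NULL`.
#' @param sigma2 current slab variance (used as the fixed value when
#'   `update_sigma2 = FALSE`, or as the chain's initial value otherwise).
#' @param config an [mcmc_config()].
#' @param variant `"scaled"` (slab variance `se^2 * sigma2`, the z-score
#'   formulation) or `"unscaled"` (slab variance `sigma2` on the effect
#'   scale, which removes the prior's dependence on sample size).
#' @param update_sigma2 sample the slab variance conjugately (default) or
#'   hold it fixed.
#' @param a_beta,b_beta inverse-gamma hyperparameters of the slab variance.
#' @param warmup use the shorter warmup chain lengths from the
#'   configuration (for intermediate EM iterations).
#' @return List with `pip`, `sigma2` (posterior mean) and `scores`
#'   (kept-sweeps x 2 matrix).
#' @export
e_step <- function(z, se = NULL, a = NULL, tau, sigma2,
                   config = mcmc_config(), variant = "scaled",
                   update_sigma2 = TRUE, a_beta = 3, b_beta = 20,
                   warmup = FALSE) {
  p <- length(z)
  a_int <- if (is.null(a)) integer(p) else as.integer(a)
  eta <- .clamp_logit(tau[1] + a_int * (if (is.null(a)) 0 else tau[2]))
  cvec <- .cvec_for_variant(variant, se, p)
  n_sweeps <- if (warmup) config$warmup_sweeps else config$n_sweeps
  burn_in <- if (warmup) config$warmup_burn_in else config$burn_in
  gibbs_estep_cpp(as.numeric(z), eta, cvec, sigma2, a_beta, b_beta,
                  n_sweeps, burn_in, update_sigma2, a_int)
}

#' M-step: logistic fit of posterior inclusion probabilities on membership
#'
#' Maximizes [expected_complete_loglik()] by iteratively reweighted least
#' squares, treating the PIPs as fractional outcomes of a logistic regression
#' on the gene set indicator (or on the intercept alone when `a` is `NULL`).
#' Under perfect separation or non-convergence the coefficients are clamped
#' at `tau_max` and flagged.
#'
#' @param pip posterior inclusion probabilities in `[0, 1]`.
#' @param a binary membership vector with both strata nonempty, or `NULL`.
#' @param tau_max coefficient clamp (default 25).
#' @return List with `tau` (length 2; `tau[2] = 0` for intercept-only) and
#'   `converged`.
#' @export
m_step <- function(pip, a = NULL, tau_max = 25) {
  stopifnot(all(pip >= 0), all(pip <= 1))
  X <- if (is.null(a)) matrix(1, length(pip), 1) else cbind(1, as.numeric(a))
  if (!is.null(a) && (all(a == 0) || all(a == 1)))
    stop("membership vector must contain both zeros and ones")
  tau <- numeric(ncol(X))
  ok <- FALSE
  for (it in seq_len(100)) {
    pi <- plogis(drop(X %*% tau))
    g <- drop(crossprod(X, pip - pi))
    if (sqrt(sum(g^2)) < 1e-8) { ok <- TRUE; break }
    w <- pmax(pi * (1 - pi), 1e-10)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    tau <- tau + clamp(step, -5, 5)
    if (any(abs(tau) > tau_max + 5)) break
  }
  clamped <- any(abs(tau) > tau_max)
  tau <- clamp(tau, -tau_max, tau_max)
  if (length(tau) == 1L) tau <- c(tau, 0)
  list(tau = tau, converged = ok && !clamped)
}

#' Louis-corrected covariance and Wald test for the enrichment coefficient
#'
#' Observed information `I_obs = I_com - I_mis`, where `I_com = sum_j x_j
#' x_j' pi_j (1 - pi_j)` is the complete-data information at `tau` and
#' `I_mis` is the sample covariance of the per-sweep complete-data score
#' vectors (which captures posterior dependence across genes induced by the
#' shared slab variance). The Wald statistic `tau1^2 / Var(tau1)` is referred
#' to the upper tail of a chi-squared distribution with one degree of
#' freedom. If `I_obs` is not positive definite a ridge `1e-6 * trace` is
#' added and flagged.
#'
#' @param score_samples kept-sweeps x 2 matrix of score vectors from
#'   [e_step()].
#' @param a binary membership vector (or `NULL` for intercept-only, in which
#'   case no test is performed).
#' @param tau fitted `(tau0, tau1)`.
#' @return List with `cov_tau` (2 x 2), `p_value`, `statistic`, `ridged`.
#' @export
louis_wald_test <- function(score_samples, a, tau) {
  if (is.null(a)) stop("louis_wald_test requires a membership vector")
  if (nrow(score_samples) < 2) stop("need at least 2 score samples")
  pi <- prior_pi(tau[1], tau[2], a)
  w <- pi * (1 - pi)
  I_com <- rbind(c(sum(w), sum(w * a)), c(sum(w * a), sum(w * a)))
  I_mis <- cov(score_samples)
  I_obs <- I_com - I_mis
  ridged <- FALSE
  ev <- eigen(I_obs, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    I_obs <- I_obs + diag(2) * 1e-6 * sum(diag(abs(I_obs)))
    ridged <- TRUE
    ev <- eigen(I_obs, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      # degenerate even after ridging: fall back to complete-data information
      I_obs <- I_com
    }
  }
  cov_tau <- solve(I_obs)
  stat <- tau[2]^2 / cov_tau[2, 2]
  list(cov_tau = cov_tau,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       statistic = stat, ridged = ridged, I_com = I_com, I_mis = I_mis)
}

# observed-data log-likelihood with per-gene slab variance sigma2 * c_j
.obs_loglik <- function(z, tau, sigma2, a, cvec) {
  eta <- .clamp_logit(tau[1] + a * tau[2])
  l1 <- plogis(eta, log.p = TRUE) + dnorm(z, 0, sqrt(sigma2 * cvec + 1), log = TRUE)
  l0 <- plogis(-eta, log.p = TRUE) + dnorm(z, 0, 1, log = TRUE)
  m <- pmax(l1, l0)
  sum(m + log(exp(l1 - m) + exp(l0 - m)))
}

.init_tau0 <- function(z) {
  frac <- mean(2 * pnorm(-abs(z)) < 0.05)
  clamp(qlogis(clamp(frac, 1e-4, 1 - 1e-4)), -5, -0.5)
}

#' Fit the enrichment model for one gene set
#'
#' EM with a Gibbs-sampling E-step: the E-step computes posterior inclusion
#' probabilities (PIPs) and the posterior mean of the slab variance with the
#' logistic prior fixed; the M-step refits `(tau0, tau1)` by logistic
#' regression on the PIPs. Iterates until `max |delta tau| < em_tol` or
#' `em_max_iter`, then runs a final E-step at the fitted `tau` and computes
#' the Louis-corrected Wald p-value for `H0: tau1 = 0`. Initialization:
#' `tau0 = logit(fraction of genes with p < 0.05)` clamped to `[-5, -0.5]`,
#' `tau1 = 0`, slab variance at its prior mean, matching the prior's
#' structure. Non-convergence is reported through `converged = FALSE`, never
#' as an error.
#'
#' @inheritParams e_step
#' @param a binary membership vector over the genes (with both strata
#'   nonempty), or `NULL` to fit the intercept-only (annotation-free) model.
#' @param tau_fixed optional `(tau0, tau1)`; when supplied, no EM is run: a
#'   single E-step is performed at these values (used for permutation nulls
#'   where the enrichment parameters are frozen).
#' @param fix_sigma2 optional positive value: hold the slab variance fixed
#'   instead of sampling it.
#' @return An object of class `enrichment_result`: `tau_hat`, `cov_tau`,
#'   `p_value`, `sigma_beta2_hat`, `pip`, `converged`, `n_em_iter`,
#'   `loglik_trace`, `score_samples`.
#' @export
fit_gene_set <- function(z, se = NULL, a, config = mcmc_config(),
                         variant = c("scaled", "unscaled"),
                         a_beta = 3, b_beta = 20, tau_fixed = NULL,
                         fix_sigma2 = NULL) {
  variant <- match.arg(variant)
  z <- as.numeric(z)
  p <- length(z)
  if (p < 2) stop("need at least 2 genes")
  stopifnot(all(is.finite(z)))
  intercept_only <- is.null(a)
  if (!intercept_only) {
    a <- as.integer(a)
    stopifnot(length(a) == p)
    if (sum(a) == 0) stop("gene set is empty after intersection with the universe")
    if (sum(a) == p) stop("gene set covers the whole universe: no contrast")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  hyper <- slab_scale(a_beta, b_beta)
  sigma2 <- if (!is.null(fix_sigma2)) fix_sigma2 else hyper$prior_mean
  update_sigma2 <- is.null(fix_sigma2)
  tau <- if (!is.null(tau_fixed)) tau_fixed else c(.init_tau0(z), 0)

  converged <- FALSE
  n_iter <- 0L
  ll <- numeric(0)
  m_ok <- TRUE
  if (is.null(tau_fixed)) {
    for (iter in seq_len(config$em_max_iter)) {
      n_iter <- iter
      es <- e_step(z, se, a, tau, sigma2, config, variant,
                   update_sigma2 = update_sigma2, a_beta = a_beta,
                   b_beta = b_beta, warmup = TRUE)
      if (update_sigma2) sigma2 <- es$sigma2
      ms <- m_step(es$pip, a)
      m_ok <- ms$converged
      delta <- max(abs(ms$tau - tau))
      tau <- ms$tau
      ll <- c(ll, .obs_loglik(z, tau, sigma2,
                              if (intercept_only) integer(p) else a,
                              .cvec_for_variant(variant, se, p)))
      if (delta < config$em_tol) { converged <- TRUE; break }
    }
  } else {
    converged <- TRUE
  }

  final <- e_step(z, se, a, tau, sigma2, config, variant,
                  update_sigma2 = update_sigma2, a_beta = a_beta,
                  b_beta = b_beta)
  if (update_sigma2) sigma2 <- final$sigma2

  if (intercept_only) {
    lw <- list(cov_tau = matrix(NA_real_, 2, 2), p_value = NA_real_,
               statistic = NA_real_, ridged = FALSE)
  } else {
    lw <- louis_wald_test(final$scores, a, tau)
  }

  structure(list(tau_hat = c(tau0 = tau[1], tau1 = tau[2]),
                 cov_tau = lw$cov_tau, p_value = lw$p_value,
                 statistic = lw$statistic,
                 sigma_beta2_hat = sigma2, pip = final$pip,
                 converged = converged && m_ok && !lw$ridged,
                 n_em_iter = n_iter, loglik_trace = ll,
                 score_samples = final$scores, variant = variant,
                 intercept_only = intercept_only),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result\n")
  cat(sprintf("  tau0 = %.4f, tau1 = %.4f\n", x$tau_hat[1], x$tau_hat[2]))
  if (!x$intercept_only)
    cat(sprintf("  Wald p-value (H0: tau1 = 0): %.3g\n", x$p_value))
  cat(sprintf("  sigma_beta2 = %.3f, EM iterations = %d, converged = %s\n",
              x$sigma_beta2_hat, x$n_em_iter, x$converged))
  invisible(x)
}
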