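#' Logistic prior probability of a gene being differentially expressed
#'
#' `pi_j = plogis(tau0 + a_j * tau1)`: the intercept `tau0` sets the DE
#' log-odds outside the gene set and `tau1` is the enrichment log odds ratio
#' for genes inside the set.
#'
#' @param tau0 intercept (log-odds of DE for genes outside the set).
#' @param tau1 enrichment coefficient (log odds ratio); default 0.
#' @param a binary membership indicator(s), 0/1.
#' @return Probability vector, computed overflow-safely.
#' @export
prior_pi <- function(tau0, tau1 = 0, a = 0) {
  stopifnot(is.finite(tau0), is.finite(tau1))
  plogis(tau0 + a * tau1)
}

# per-gene log densities of the two mixture components on the z scale
.mix_logdens <- function(z, sigma_beta2) {
  list(slab = dnorm(z, 0, sqrt(sigma_beta2 + 1), log = TRUE),
       spike = dnorm(z, 0, 1, log = TRUE))
}

#' Marginal log-likelihood of z-scores under the spike-and-slab mixture
#'
#' `sum_j log[pi_j N(z_j; 0, sigma_beta2 + 1) + (1 - pi_j) N(z_j; 0, 1)]`
#' evaluated in log space with log-sum-exp. Mixing probabilities are clamped
#' to `[1e-8, 1 - 1e-8]` so the objective stays finite under separation.
#'
#' @param z numeric vector of z-scores.
#' @param tau0,tau1 logistic prior parameters.
#' @param sigma_beta2 slab variance scaling factor (> 0).
#' @param a binary membership vector (default all zero).
#' @return The observed-data log-likelihood (a scalar).
#' @export
zscore_mixture_loglik <- function(z, tau0, tau1 = 0, sigma_beta2,
                                  a = integer(length(z))) {
  if (!is.finite(sigma_beta2) || sigma_beta2 <= 0)
    stop("sigma_beta2 must be positive")
  stopifnot(all(is.finite(z)))
  eta <- .clamp_logit(tau0 + a * tau1)
  lp1 <- plogis(eta, log.p = TRUE)
  lp0 <- plogis(-eta, log.p = TRUE)
  d <- .mix_logdens(z, sigma_beta2)
  l1 <- lp1 + d$slab
  l0 <- lp0 + d$spike
  m <- pmax(l1, l0)
  sum(m + log(exp(l1 - m) + exp(l0 - m)))
}

#' Posterior probability that a gene is DE given its z-score
#'
#' The spike-and-slab responsibility with the effect size integrated out:
#' `pi N(z; 0, s+1) / [pi N(z; 0, s+1) + (1-pi) N(z; 0, 1)]`.
#'
#' @param z numeric vector of z-scores.
#' @param pi prior DE probability (vector or scalar, recycled).
#' @param sigma_beta2 slab variance scaling factor (>= 0).
#' @return Probability vector.
#' @export
spike_slab_responsibility <- function(z, pi, sigma_beta2) {
  stopifnot(all(pi >= 0), all(pi <= 1), sigma_beta2 >= 0)
  d <- .mix_logdens(z, sigma_beta2)
  out <- plogis(qlogis(clamp(pi, 1e-300, 1 - 1e-16)) + d$slab - d$spike)
  out[pi == 0] <- 0
  out[pi == 1] <- 1
  out
}

#' Expected complete-data log-likelihood of the logistic prior
#'
#' The EM M-step objective: `sum_j [pip_j log pi_j + (1 - pip_j) log(1 -
#' pi_j)]` with `pi_j` from [prior_pi()]. Log arguments are floored at 1e-12.
#'
#' @param pip posterior inclusion probabilities in `[0, 1]`.
#' @param tau0,tau1 logistic prior parameters.
#' @param a binary membership vector.
#' @return Scalar objective value.
#' @export
expected_complete_loglik <- function(pip, tau0, tau1 = 0,
                                     a = integer(length(pip))) {
  stopifnot(all(pip >= 0), all(pip <= 1))
  pi <- prior_pi(tau0, tau1, a)
  sum(pip * log(pmax(pi, 1e-12)) + (1 - pip) * log(pmax(1 - pi, 1e-12)))
}

#' Default inverse-gamma hyperparameters for the slab variance
#'
#' The slab scaling factor carries an inverse-gamma prior `InvG(a_beta,
#' b_beta)` with defaults (3, 20), giving prior mean `b_beta / (a_beta - 1)
#' = 10`; `a_beta > 2` guarantees the prior variance exists.
#'
#' @param a_beta,b_beta inverse-gamma shape and rate.
#' @return A list with `a_beta`, `b_beta` and the implied `prior_mean`.
#' @export
slab_scale <- function(a_beta = 3, b_beta = 20) {
  stopifnot(a_beta > 2, b_beta > 0)
  list(a_beta = a_beta, b_beta = b_beta, prior_mean = b_beta / (a_beta - 1))
}
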