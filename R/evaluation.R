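#' Power at a fixed false discovery rate
#'
#' In `"true_fdr"` mode thresholds are swept over the observed scores and
#' the largest call set whose realized false discovery proportion does not
#' exceed the target is selected; power is the fraction of true signals in
#' that set. In `"empirical_fdr"` mode the threshold comes from a
#' permutation-null score pool via the empirical FDR. Larger scores are more
#' significant (negate p-values before calling).
#'
#' @param scores numeric vector, larger = more significant.
#' @param truth binary vector of true signals.
#' @param fdr_target target FDR (default 0.05).
#' @param mode `"true_fdr"` (default) or `"empirical_fdr"`.
#' @param null_scores permutation-null scores (required for
#'   `"empirical_fdr"`).
#' @param n_perm number of permutations behind `null_scores`.
#' @return Power in `[0, 1]`.
#' @export
power_at_fdr <- function(scores, truth, fdr_target = 0.05,
                         mode = c("true_fdr", "empirical_fdr"),
                         null_scores = NULL, n_perm = NULL) {
  mode <- match.arg(mode)
  truth <- as.logical(truth)
  if (!any(truth)) stop("no true signals: power undefined")
  stopifnot(length(scores) == length(truth))
  if (mode == "true_fdr") {
    ord <- order(scores, decreasing = TRUE)
    fdp <- cumsum(!truth[ord]) / seq_along(ord)
    k <- max(c(0L, which(fdp <= fdr_target)))
    if (k == 0) return(0)
    sum(truth[ord][seq_len(k)]) / sum(truth)
  } else {
    if (is.null(null_scores) || is.null(n_perm))
      stop("empirical_fdr mode needs null_scores and n_perm")
    fdr <- empirical_fdr(-scores, -null_scores, n_perm)
    called <- fdr <= fdr_target
    sum(truth & called) / sum(truth)
  }
}

#' Permutation null for DE calls with frozen enrichment parameters
#'
#' For each permutation the cell labels are shuffled, the internal NB Wald
#' DE test is rerun, and a single E-step is performed with the enrichment
#' parameters frozen at their estimates from the unpermuted fit (no
#' re-estimation, which would produce overly liberal nulls). The pooled null
#' PIPs feed the empirical FDR of DE calls.
#'
#' @param counts genes x cells count matrix.
#' @param labels per-cell group labels (1/2).
#' @param a binary annotation vector over the genes.
#' @param fitted an `enrichment_result` from the unpermuted data, supplying
#'   `tau_hat` (and the slab variance).
#' @param n_perm number of label permutations (default 10).
#' @param config an [mcmc_config()].
#' @param reestimate_tau if `TRUE`, re-runs the full EM on each permutation
#'   instead of freezing `tau` (for studying the liberal behaviour of
#'   re-estimation).
#' @return Matrix of null PIPs (genes x permutations) for the genes retained
#'   by the DE test in each permutation; dropped genes carry `NA`.
#' @export
de_permutation_null <- function(counts, labels, a, fitted, n_perm = 10,
                                config = mcmc_config(),
                                reestimate_tau = FALSE) {
  p <- nrow(counts)
  out <- matrix(NA_real_, p, n_perm)
  for (k in seq_len(n_perm)) {
    perm <- sample(labels)
    st <- internal_de_test(counts, perm)
    keep <- st$flag != 2L & is.finite(st$z)
    fit <- if (reestimate_tau) {
      fit_gene_set(st$z[keep], st$se[keep], a[keep], config = config)
    } else {
      fit_gene_set(st$z[keep], st$se[keep], a[keep], config = config,
                   tau_fixed = unname(fitted$tau_hat),
                   fix_sigma2 = fitted$sigma_beta2_hat)
    }
    out[keep, k] <- fit$pip
  }
  out
}

#' Jaccard index of two top-k gene lists
#'
#' @param list_a,list_b ranked gene identifier vectors (most significant
#'   first).
#' @param k depth of the comparison.
#' @return `|A ∩ B| / |A ∪ B|` over the top-k of each list.
#' @export
jaccard_topk <- function(list_a, list_b, k) {
  stopifnot(k <= length(list_a), k <= length(list_b))
  a <- list_a[seq_len(k)]
  b <- list_b[seq_len(k)]
  length(intersect(a, b)) / length(union(a, b))
}

#' Rank-based ROC AUC
#'
#' The probability that a randomly chosen true signal outranks a randomly
#' chosen non-signal, with ties split.
#'
#' @param scores numeric vector, larger = more significant.
#' @param truth binary vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- desk-scale study drivers ------------------------------------------

#' Desk-scale GSE power study on simulated counts
#'
#' Reproduces the count-level enrichment power protocol at reduced replicate
#' numbers: each replicate simulates ZTNB counts with dropout in
#' reference-free mode (10,000 genes, 174 cells split 105/69 by default),
#' assigns DE truth through the logistic model, computes summary statistics
#' with the internal NB Wald test, fits the enrichment model on the
#' replicate's gene set, and records the Wald p-value. Power at the target
#' FDR is computed over the pooled enriched and null replicates with
#' realized-FDP thresholding ([power_at_fdr()], `"true_fdr"` mode).
#'
#' @param n_enriched,n_null numbers of enriched (`tau1 = tau1_alt`) and null
#'   (`tau1 = 0`) replicates; defaults 100 and 400.
#' @param p,group_sizes problem size per replicate.
#' @param tau0 baseline DE log-odds (default -2).
#' @param tau1_alt enrichment coefficient of the enriched replicates
#'   (default 0.5).
#' @param cr gene set coverage rate (default 0.1).
#' @param fdr_target FDR at which power is evaluated (default 0.05).
#' @param config MCMC/EM configuration; the default uses a final E-step of
#'   500 sweeps (100 burn-in), lighter warmup E-steps of 200 sweeps during
#'   the EM iterations, and at most 10 EM iterations per fit, sized for a
#'   multi-hundred replicate study.
#' @param seed master seed.
#' @return List with `power`, and `table` (per-replicate `p_value`,
#'   `enriched`, `tau1_hat`, `converged`).
#' @export
gse_power_study <- function(n_enriched = 100, n_null = 400, p = 10000,
                            group_sizes = c(105, 69), tau0 = -2,
                            tau1_alt = 0.5, cr = 0.1, fdr_target = 0.05,
                            config = mcmc_config(n_sweeps = 500,
                                                 burn_in = 100,
                                                 em_max_iter = 10,
                                                 warmup_sweeps = 200,
                                                 warmup_burn_in = 50),
                            seed = 1) {
  n_rep <- n_enriched + n_null
  enriched <- rep(c(TRUE, FALSE), c(n_enriched, n_null))
  pv <- t1 <- rep(NA_real_, n_rep)
  conv <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(derive_seed(seed, paste0("power-rep", r)))
    rf <- reference_free_params(p, sum(group_sizes))
    truth <- assign_truth(p, cr, tau0, if (enriched[r]) tau1_alt else 0)
    sim <- simulate_counts(rf$params, rf$dropout, truth, group_sizes,
                           depths = rf$depths)
    st <- internal_de_test(sim$counts, sim$labels)
    keep <- st$flag != 2L & is.finite(st$z)
    fit <- fit_gene_set(st$z[keep], st$se[keep], truth$a[keep],
                        config = config)
    pv[r] <- fit$p_value
    t1[r] <- fit$tau_hat[2]
    conv[r] <- fit$converged
  }
  power <- power_at_fdr(-pv, enriched, fdr_target)
  list(power = power,
       table = data.frame(p_value = pv, enriched = enriched, tau1_hat = t1,
                          converged = conv))
}

#' Null-calibration study of enrichment p-values
#'
#' Fits the enrichment model on `n_fits` independent model-simulated data
#' sets with no enrichment (`tau1 = 0`) and returns the Wald p-values, for
#' KS-uniformity and genomic-control checks.
#'
#' The default slab variance `(3.5 / 0.3)^2` puts the study in the signal
#' regime of the count-level simulation design: DE effects with standard
#' deviation 3.5 observed through standard errors around 0.3, as the
#' 174-cell NB Wald stage produces. The genomic control factor is a
#' median-based statistic whose sampling noise decays slowly (about
#' `2.33 / sqrt(n_fits)`), so the default uses 2000 fits to measure it to
#' about 0.05.
#'
#' @param n_fits number of null fits (default 2000).
#' @param p genes per fit (default 2000).
#' @param tau0 baseline DE log-odds (default -2).
#' @param cr coverage rate (default 0.1).
#' @param sigma_beta2 generating slab variance (default `(3.5 / 0.3)^2`).
#' @param config MCMC/EM configuration.
#' @param seed master seed.
#' @return Numeric vector of `n_fits` p-values.
#' @export
null_calibration_study <- function(n_fits = 2000, p = 2000, tau0 = -2,
                                   cr = 0.1, sigma_beta2 = (3.5 / 0.3)^2,
                                   config = mcmc_config(n_sweeps = 500,
                                                        burn_in = 100,
                                                        em_max_iter = 12,
                                                        warmup_sweeps = 200,
                                                        warmup_burn_in = 50),
                                   seed = 1) {
  pv <- rep(NA_real_, n_fits)
  for (r in seq_len(n_fits)) {
    set.seed(derive_seed(seed, paste0("null-rep", r)))
    truth <- assign_truth(p, cr, tau0, 0)
    st <- simulate_summary_stats(truth, se = 1, sigma_beta2 = sigma_beta2)
    fit <- fit_gene_set(st$z, st$se, truth$a, config = config)
    pv[r] <- fit$p_value
  }
  pv
}

#' Parameter-recovery study for the enrichment coefficient
#'
#' Simulates summary statistics directly from the mixture model and refits,
#' recording the enrichment estimate and whether the 95% Wald interval
#' covers the generating value.
#'
#' @param n_seeds number of replicates (default 50).
#' @param p genes per replicate (default 10000).
#' @param tau0,tau1 generating parameters (defaults -2, 1).
#' @param cr coverage rate (default 0.1).
#' @param sigma_beta2 generating slab variance (default 9).
#' @param config MCMC/EM configuration.
#' @param seed master seed.
#' @return `data.frame` with `tau1_hat`, `se_tau1`, `covered`.
#' @export
recovery_study <- function(n_seeds = 50, p = 10000, tau0 = -2, tau1 = 1,
                           cr = 0.1, sigma_beta2 = 9,
                           config = mcmc_config(n_sweeps = 500,
                                                burn_in = 100,
                                                em_max_iter = 15,
                                                warmup_sweeps = 200,
                                                warmup_burn_in = 50),
                           seed = 1) {
  est <- se <- rep(NA_real_, n_seeds)
  for (r in seq_len(n_seeds)) {
    set.seed(derive_seed(seed, paste0("recov-rep", r)))
    truth <- assign_truth(p, cr, tau0, tau1)
    st <- simulate_summary_stats(truth, se = 1, sigma_beta2 = sigma_beta2)
    fit <- fit_gene_set(st$z, st$se, truth$a, config = config)
    est[r] <- fit$tau_hat[2]
    se[r] <- sqrt(fit$cov_tau[2, 2])
  }
  data.frame(tau1_hat = est, se_tau1 = se,
             covered = abs(est - tau1) <= qnorm(0.975) * se)
}

#' FDR-calibration study for PIP-based DE calls
#'
#' On model-simulated data, calls DE genes at a nominal Bayesian FDR and
#' records the realized false discovery proportion per replicate.
#'
#' @param n_seeds number of replicates (default 50).
#' @param p genes per replicate (default 2000).
#' @param tau0,tau1 generating parameters (defaults -2, 1).
#' @param cr coverage rate (default 0.1).
#' @param sigma_beta2 generating slab variance (default 9).
#' @param fdr_target nominal Bayesian FDR (default 0.05).
#' @param config MCMC/EM configuration.
#' @param seed master seed.
#' @return `data.frame` with `fdp` and `n_calls` per replicate.
#' @export
fdr_calibration_study <- function(n_seeds = 50, p = 2000, tau0 = -2,
                                  tau1 = 1, cr = 0.1, sigma_beta2 = 9,
                                  fdr_target = 0.05,
                                  config = mcmc_config(n_sweeps = 500,
                                                       burn_in = 100,
                                                       em_max_iter = 12,
                                                       warmup_sweeps = 200,
                                                       warmup_burn_in = 50),
                                  seed = 1) {
  fdp <- nc <- rep(NA_real_, n_seeds)
  for (r in seq_len(n_seeds)) {
    set.seed(derive_seed(seed, paste0("fdr-rep", r)))
    truth <- assign_truth(p, cr, tau0, tau1)
    st <- simulate_summary_stats(truth, se = 1, sigma_beta2 = sigma_beta2)
    fit <- fit_gene_set(st$z, st$se, truth$a, config = config)
    calls <- bayesian_fdr(fit$pip, fdr_target)
    nc[r] <- calls$n_calls
    fdp[r] <- if (calls$n_calls > 0)
      sum(calls$calls & truth$gamma_true == 0) / calls$n_calls else 0
  }
  data.frame(fdp = fdp, n_calls = nc)
}

#' Sensitivity of the enrichment fit to the slab-variance prior
#'
#' Refits one gene set across inverse-gamma priors whose means span several
#' orders of magnitude (0.001, 0.1, 1, 10, 100 by default, with shape fixed
#' at 3 so `b_beta = mean * (a_beta - 1)`), reporting the stability of the
#' enrichment estimate and p-value.
#'
#' @param stats summary-statistics table.
#' @param a binary membership vector.
#' @param prior_means prior means to sweep.
#' @param config an [mcmc_config()].
#' @return `data.frame` with `prior_mean`, `a_beta`, `b_beta`, `tau1_hat`,
#'   `p_value`, `sigma_beta2_hat`.
#' @export
sensitivity_scan <- function(stats, a,
                             prior_means = c(0.001, 0.1, 1, 10, 100),
                             config = mcmc_config()) {
  rows <- lapply(prior_means, function(m) {
    b <- m * 2  # a_beta = 3 fixed
    fit <- fit_gene_set(stats$z, stats$se, a, config = config,
                        a_beta = 3, b_beta = b)
    data.frame(prior_mean = m, a_beta = 3, b_beta = b,
               tau1_hat = fit$tau_hat[2], p_value = fit$p_value,
               sigma_beta2_hat = fit$sigma_beta2_hat)
  })
  do.call(rbind, rows)
}
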