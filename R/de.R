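#' Bayesian FDR thresholding of posterior inclusion probabilities
#'
#' Direct posterior-probability approach: genes are sorted by PIP in
#' decreasing order; the expected FDR of the top-k call set is the mean of
#' the local false discovery rates `1 - pip` over it; the call set is the
#' largest k whose expected FDR does not exceed the target. Ties are broken
#' by the stable input gene order.
#'
#' @param pip posterior inclusion probabilities.
#' @param target target FDR in (0, 1).
#' @return A list of class `de_call_set`: `threshold` (smallest PIP among the
#'   calls, or `NA` when nothing is called), `calls` (binary vector in input
#'   order), `n_calls`, `expected_fdr` (of the call set), `local_fdr`
#'   (`1 - pip` per gene), `bayes_fdr` (expected FDR of each top-k set in
#'   sorted order).
#' @export
bayesian_fdr <- function(pip, target) {
  stopifnot(target > 0 || target == 0, target < 1, all(pip >= 0), all(pip <= 1))
  ord <- order(pip, decreasing = TRUE)
  cum_fdr <- cumsum(1 - pip[ord]) / seq_along(pip)
  k <- max(c(0L, which(cum_fdr <= target)))
  calls <- logical(length(pip))
  if (k > 0) calls[ord[seq_len(k)]] <- TRUE
  structure(list(threshold = if (k > 0) pip[ord[k]] else NA_real_,
                 calls = calls, n_calls = k,
                 expected_fdr = if (k > 0) cum_fdr[k] else 0,
                 local_fdr = 1 - pip, bayes_fdr = cum_fdr),
            class = "de_call_set")
}

#' DE analysis with a pre-selected gene set as the annotation
#'
#' Fits the enrichment model on the supplied gene set, takes the posterior
#' inclusion probabilities from the final E-step, and calls DE genes by
#' [bayesian_fdr()].
#'
#' @param stats summary-statistics table.
#' @param a binary membership vector (nonempty).
#' @param config an [mcmc_config()].
#' @param fdr_target Bayesian FDR target for calls (default 0.05).
#' @param ... further arguments to [fit_gene_set()].
#' @return List with the `enrichment_result` (`fit`) and the `de_call_set`
#'   (`calls`).
#' @export
de_with_annotation <- function(stats, a, config = mcmc_config(),
                               fdr_target = 0.05, ...) {
  if (sum(a) == 0) stop("empty annotation")
  fit <- fit_gene_set(stats$z, stats$se, a, config = config, ...)
  list(fit = fit, calls = bayesian_fdr(fit$pip, fdr_target))
}

#' Annotation-free DE analysis
#'
#' Fits the intercept-only model (the membership column is dropped, so only
#' the baseline DE log-odds `tau0` is estimated) and calls DE genes from the
#' resulting PIPs.
#'
#' @inheritParams de_with_annotation
#' @return List with `fit` and `calls` as in [de_with_annotation()].
#' @export
de_without_annotation <- function(stats, config = mcmc_config(),
                                  fdr_target = 0.05, ...) {
  fit <- fit_gene_set(stats$z, stats$se, a = NULL, config = config, ...)
  list(fit = fit, calls = bayesian_fdr(fit$pip, fdr_target))
}

#' Bayesian model averaging of PIPs across gene sets
#'
#' Aggregates per-gene DE evidence across fitted gene sets:
#' `pip_j(BMA) = sum_s w_s pip_j(s)` with weights proportional to a
#' BIC-style approximation of each set's model evidence (from the final
#' observed-data log-likelihood with 3 free parameters), or uniform weights.
#'
#' @param results list of `enrichment_result` objects over the same gene
#'   universe.
#' @param weights `"bic"` (default) or `"uniform"`.
#' @return List with the averaged `pip` vector and the `weights` used.
#' @export
bma_pip <- function(results, weights = c("bic", "uniform")) {
  weights <- match.arg(weights)
  stopifnot(length(results) >= 1)
  pips <- vapply(results, function(r) r$pip, numeric(length(results[[1]]$pip)))
  pips <- matrix(pips, ncol = length(results))
  if (weights == "uniform" || length(results) == 1L) {
    w <- rep(1 / length(results), length(results))
  } else {
    ll <- vapply(results, function(r) {
      if (length(r$loglik_trace)) r$loglik_trace[length(r$loglik_trace)]
      else stop("results lack a log-likelihood trace; refit without tau_fixed")
    }, numeric(1))
    p <- length(results[[1]]$pip)
    half_bic <- ll - 1.5 * log(p)  # -BIC/2 with 3 parameters
    w <- exp(half_bic - max(half_bic))
    w <- w / sum(w)
  }
  list(pip = drop(pips %*% w), weights = w)
}
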