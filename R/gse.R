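#' Scan a gene set collection for enrichment
#'
#' Applies [fit_gene_set()] independently to every set in the collection.
#' Each set draws its own seed deterministically from the master seed and the
#' set name, so results are identical regardless of scan order and are not
#' perturbed when sets are added or removed. Per-set failures are recorded
#' and the scan continues. With `n_perm > 0` the scan is repeated on
#' permuted collections (see [permute_set_labels()]) and a per-set empirical
#' FDR column is added from the pooled permutation-null p-values.
#'
#' @param stats summary-statistics table (see [read_summary_stats()]); its
#'   `gene_id` order defines the universe and must match
#'   `collection$universe`.
#' @param collection a pruned `gene_set_collection`.
#' @param config an [mcmc_config()]; its `seed` acts as the master seed.
#' @param n_perm number of label permutations for the empirical FDR
#'   (0 disables; the conventional choice is 10).
#' @param perm_mode `"joint"` (one gene relabeling applied to all sets,
#'   preserving pairwise overlaps exactly) or `"per_set"` (independent
#'   shuffles of fixed size per set).
#' @param variant model variant passed to [fit_gene_set()].
#' @return A list of class `gse_scan` with `table` (one row per set:
#'   `set_name`, `size`, `coverage`, `tau0`, `tau1`, `se_tau1`, `p_value`,
#'   `sigma_beta2`, `converged`, and `empirical_fdr` when permutations were
#'   run), `results` (named list of `enrichment_result`), and `null_p`
#'   (pooled permutation-null p-values, or `NULL`).
#' @export
run_gse_scan <- function(stats, collection, config = mcmc_config(),
                         n_perm = 0, perm_mode = c("joint", "per_set"),
                         variant = "scaled") {
  perm_mode <- match.arg(perm_mode)
  stopifnot(identical(stats$gene_id, collection$universe))
  master <- if (is.null(config$seed)) 0L else config$seed
  scan_one <- function(coll, seed_salt = "") {
    nm <- names(coll$sets)
    res <- vector("list", length(nm))
    names(res) <- nm
    for (s in nm) {
      cfg <- config
      cfg$seed <- derive_seed(master, paste0(seed_salt, s))
      res[[s]] <- tryCatch(
        fit_gene_set(stats$z, stats$se, set_membership(coll, s),
                     config = cfg, variant = variant),
        error = function(e) e)
    }
    res
  }
  results <- scan_one(collection)
  table <- .scan_table(results, collection)
  null_p <- NULL
  if (n_perm > 0) {
    perms <- permute_set_labels(collection, n_perm, mode = perm_mode,
                                seed = derive_seed(master, "permutations"))
    null_p <- unlist(lapply(seq_along(perms), function(k) {
      pr <- scan_one(perms[[k]], seed_salt = paste0("perm", k, ":"))
      vapply(pr, function(r) if (inherits(r, "error")) NA_real_ else r$p_value,
             numeric(1))
    }), use.names = FALSE)
    null_p <- null_p[is.finite(null_p)]
    table$empirical_fdr <- empirical_fdr(table$p_value, null_p, n_perm)
  }
  structure(list(table = table, results = results, null_p = null_p),
            class = "gse_scan")
}

.scan_table <- function(results, collection) {
  nm <- names(results)
  grab <- function(f) vapply(results, function(r)
    if (inherits(r, "error")) NA_real_ else f(r), numeric(1))
  data.frame(
    set_name = nm,
    size = as.integer(set_sizes(collection)[nm]),
    coverage = as.numeric(coverage_rates(collection)[nm]),
    tau0 = grab(function(r) r$tau_hat[1]),
    tau1 = grab(function(r) r$tau_hat[2]),
    se_tau1 = grab(function(r) sqrt(r$cov_tau[2, 2])),
    p_value = grab(function(r) r$p_value),
    sigma_beta2 = grab(function(r) r$sigma_beta2_hat),
    converged = vapply(results, function(r)
      if (inherits(r, "error")) FALSE else isTRUE(r$converged), logical(1)),
    failed = vapply(results, function(r) inherits(r, "error"), logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.gse_scan <- function(x, ...) {
  cat("gse_scan over", nrow(x$table), "gene set(s)\n")
  print(head(x$table[order(x$table$p_value), ], 10))
  invisible(x)
}

#' Permute gene set labels
#'
#' Builds permutation-null collections for the empirical FDR. In `"joint"`
#' mode a single permutation of the gene labels is applied to every set
#' simultaneously, which preserves all pairwise set overlaps exactly (so
#' correlations between overlapping sets are comparable between real and
#' permuted data). In `"per_set"` mode each set's membership is shuffled
#' independently across the universe. Both modes preserve every set's size
#' exactly.
#'
#' @param collection a `gene_set_collection`.
#' @param n_perm number of permutations (default 10).
#' @param mode `"joint"` (default) or `"per_set"`.
#' @param seed optional integer seed.
#' @return A list of `n_perm` permuted `gene_set_collection` objects.
#' @export
permute_set_labels <- function(collection, n_perm = 10,
                               mode = c("joint", "per_set"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- length(collection$universe)
  lapply(seq_len(n_perm), function(k) {
    out <- collection
    if (mode == "joint") {
      relabel <- sample.int(p)
      out$sets <- lapply(collection$sets, function(idx) sort(relabel[idx]))
    } else {
      out$sets <- lapply(collection$sets, function(idx)
        sort(sample.int(p, length(idx))))
    }
    out
  })
}

#' Empirical FDR from a permutation-null p-value pool
#'
#' `FDR(t) = [#null p <= t / n_perm] / max(1, #observed p <= t)`, evaluated
#' at each observed p-value, capped at 1, and made monotone non-increasing in
#' the p-value threshold by a cumulative minimum taken from the largest
#' threshold downward.
#'
#' @param observed_p observed enrichment p-values.
#' @param null_p pooled null p-values from permuted scans.
#' @param n_perm number of permutations that produced the pool.
#' @return Per-observation empirical FDR values in `[0, 1]`.
#' @export
empirical_fdr <- function(observed_p, null_p, n_perm) {
  if (length(null_p) == 0) stop("empty permutation-null pool")
  ord <- order(observed_p, decreasing = TRUE)
  fdr <- numeric(length(observed_p))
  n_obs_le <- vapply(observed_p, function(t) sum(observed_p <= t), numeric(1))
  n_null_le <- vapply(observed_p, function(t) sum(null_p <= t), numeric(1))
  raw <- pmin(1, (n_null_le / n_perm) / pmax(1, n_obs_le))
  fdr[ord] <- cummin(raw[ord])
  fdr
}

#' Genomic control factor of a p-value set
#'
#' Converts p-values to chi-squared(1) statistics and divides their median by
#' the theoretical null median `qchisq(0.5, 1) = 0.4549364`. Values near 1
#' indicate calibrated p-values.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return The genomic control factor (positive scalar).
#' @export
genomic_control_lambda <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  stopifnot(all(p > 0), all(p <= 1))
  stats <- qchisq(p, df = 1, lower.tail = FALSE)
  median(stats) / qchisq(0.5, df = 1)
}

#' Hypergeometric over-representation test
#'
#' Counts DE genes (input p-value below `de_threshold`) inside and outside
#' the gene set and computes the one-sided over-representation p-value from
#' the hypergeometric tail of the 2 x 2 table.
#'
#' @param stats summary-statistics table.
#' @param a binary membership vector over the genes of `stats`.
#' @param de_threshold DE p-value cutoff (default 0.05).
#' @return One-sided p-value.
#' @export
hypergeometric_gse <- function(stats, a, de_threshold = 0.05) {
  stopifnot(de_threshold > 0, de_threshold < 1)
  de <- stats$p < de_threshold
  k <- sum(de & a == 1)
  stats::phyper(k - 1, m = sum(de), n = sum(!de), k = sum(a == 1),
                lower.tail = FALSE)
}
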