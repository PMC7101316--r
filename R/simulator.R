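#' Zero-truncated negative binomial parameter estimation by method of moments
#'
#' Estimates, for each gene, the mean expression rate per unit depth
#' `lambda_j` and NB dispersion (size) `phi_j` from the nonzero counts only,
#' iterating the truncation-corrected moment updates
#' \deqn{\lambda^{(t+1)} = \sum_i Y_{ij} (1 - f_0(\lambda N_i, \phi)) / \sum_i N_i}
#' \deqn{\phi^{(t+1)} = \sum_i (\lambda N_i)^2 / [\sum_i Y_{ij}^2 (1 - f_0) -
#'   \sum_i (\lambda N_i)^2 - \sum_i \lambda N_i]}
#' where `f_0(mu, phi)` is the NB probability of a zero count and sums run
#' over cells with nonzero counts. Genes with fewer than 3 nonzero counts
#' are excluded; genes whose dispersion update diverges (negative or
#' non-finite) fall back to a plain method of moments on the nonzero counts
#' ignoring truncation, and are flagged.
#'
#' @param counts genes x cells count matrix.
#' @param depths per-cell total counts `N_i` (default `colSums(counts)`).
#' @param max_iter,tol fixed-point iteration controls (relative change).
#' @return A `data.frame` with `lambda`, `phi`, `converged`, `excluded`.
#' @export
ztnb_mom_estimate <- function(counts, depths = colSums(counts),
                              max_iter = 500, tol = 1e-6) {
  p <- nrow(counts)
  lambda <- rep(NA_real_, p); phi <- rep(NA_real_, p)
  converged <- logical(p); excluded <- logical(p)
  for (j in seq_len(p)) {
    y <- counts[j, ]
    nz <- which(y > 0)
    if (length(nz) < 3) { excluded[j] <- TRUE; next }
    y <- y[nz]; N <- depths[nz]
    lam <- sum(y) / sum(N)
    ph <- 2
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      mu <- lam * N
      f0 <- dnbinom(0, size = ph, mu = mu)
      lam_new <- sum(y * (1 - f0)) / sum(N)
      mu <- lam * N  # Eq. updates use the current-iteration lambda
      denom <- sum(y^2 * (1 - f0)) - sum(mu^2) - sum(mu)
      ph_new <- sum(mu^2) / denom
      if (!is.finite(ph_new) || ph_new <= 0 || !is.finite(lam_new) ||
          lam_new <= 0) { ok <- FALSE; break }
      rel <- max(abs(lam_new - lam) / lam, abs(ph_new - ph) / ph)
      lam <- lam_new; ph <- ph_new
      if (rel < tol) { ok <- TRUE; break }
    }
    if (!ok || !is.finite(ph) || ph <= 0) {
      # fallback: moments of the nonzero counts, ignoring truncation
      lam <- sum(y) / sum(N)
      mu <- lam * N
      dd <- sum((y - mu)^2 - mu)
      ph <- if (dd > 0) sum(mu^2) / dd else 1e4
      converged[j] <- FALSE
    } else {
      converged[j] <- TRUE
    }
    lambda[j] <- lam; phi[j] <- clamp(ph, 1e-4, 1e6)
  }
  data.frame(lambda = lambda, phi = phi, converged = converged,
             excluded = excluded)
}

#' @importFrom stats dnbinom
NULL

#' Fit the cell- and gene-specific dropout model
#'
#' Logistic regression of the zero indicator `z_ij = 1(count == 0)` on a
#' cubic B-spline basis (5 degrees of freedom) in the gene's average log2
#' counts-per-million `A_j`, the log cell depth `log(N_i)`, and their
#' interaction, so the dropout probability is both gene- and cell-specific.
#'
#' @param counts genes x cells count matrix.
#' @param depths per-cell total counts.
#' @param df spline degrees of freedom (default 5).
#' @param A optional per-gene abundance covariate (average log2 CPM); by
#'   default computed from `counts`, but callers with better pre-dropout
#'   abundance estimates can supply their own.
#' @return An object of class `dropout_fit` holding the fitted coefficients
#'   and spline basis; use [predict_dropout()] to evaluate it.
#' @export
fit_dropout_model <- function(counts, depths = colSums(counts), df = 5,
                              A = NULL) {
  if (ncol(counts) < 2 || nrow(counts) < 50)
    stop("need at least 2 cells and 50 genes to fit the dropout model")
  if (is.null(A)) A <- log2(rowSums(counts) / sum(depths) * 1e6 + 0.5)
  stopifnot(length(A) == nrow(counts))
  logN <- log(depths)
  zero <- as.numeric(as.vector(counts == 0))
  A_long <- rep(A, times = ncol(counts))
  logN_long <- rep(logN, each = nrow(counts))
  basis <- splines::bs(A_long, df = df)
  X <- cbind(1, basis, logN_long, basis * logN_long)
  flagged <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, zero, family = binomial(),
            control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  coef <- fit$coefficients
  coef[!is.finite(coef)] <- 0
  coef <- clamp(coef, -50, 50)  # complete separation: clamp, flag
  structure(list(coef = coef, df = df,
                 knots = attr(basis, "knots"),
                 boundary_knots = attr(basis, "Boundary.knots"),
                 degree = attr(basis, "degree"),
                 A_range = range(A),
                 boundary_flag = flagged || any(abs(coef) >= 50)),
            class = "dropout_fit")
}

#' Parametric reference-free dropout surface
#'
#' A logistic surface in the gene's expected count at the reference depth and
#' the centred log depth, with a negative slope in expression (lowly
#' expressed genes drop out more) and a negative slope in depth (deeper
#' cells drop out less):
#' `logit p = eta0 + eta_expr * log10(lambda * ref_depth + 1) +
#' eta_depth * (log N - log ref_depth)`.
#'
#' @param eta0 intercept (default 1.5).
#' @param eta_expr expression slope (default -1).
#' @param eta_depth depth slope (default -0.5).
#' @param ref_depth reference depth (default 1e6).
#' @return An object of class `dropout_surface`.
#' @export
dropout_surface <- function(eta0 = 1.5, eta_expr = -1, eta_depth = -0.5,
                            ref_depth = 1e6) {
  structure(list(eta0 = eta0, eta_expr = eta_expr, eta_depth = eta_depth,
                 ref_depth = ref_depth),
            class = "dropout_surface")
}

#' Predict cell x gene dropout probabilities
#'
#' @param model a `dropout_fit` or `dropout_surface`.
#' @param lambda per-gene expected rate per unit depth (fold change already
#'   applied where relevant).
#' @param depths per-cell total counts.
#' @param ... method-specific arguments (`dropout_fit` accepts `A`, an
#'   explicit abundance covariate overriding the `lambda`-derived one).
#' @return genes x cells matrix of dropout probabilities in (0, 1), clamped
#'   to `[1e-6, 1 - 1e-6]`.
#' @export
predict_dropout <- function(model, lambda, depths, ...) {
  UseMethod("predict_dropout")
}

#' @export
predict_dropout.dropout_surface <- function(model, lambda, depths, ...) {
  eta <- outer(model$eta0 +
                 model$eta_expr * log10(lambda * model$ref_depth + 1),
               model$eta_depth * (log(depths) - log(model$ref_depth)), `+`)
  clamp(plogis(eta), 1e-6, 1 - 1e-6)
}

#' @export
predict_dropout.dropout_fit <- function(model, lambda, depths, A = NULL, ...) {
  if (is.null(A)) A <- log2(lambda * 1e6 + 0.5)
  A <- clamp(A, model$A_range[1], model$A_range[2])
  logN <- log(depths)
  A_long <- rep(A, times = length(depths))
  logN_long <- rep(logN, each = length(A))
  basis <- splines::bs(A_long, knots = model$knots, degree = model$degree,
                       Boundary.knots = model$boundary_knots)
  X <- cbind(1, basis, logN_long, basis * logN_long)
  pr <- plogis(drop(X %*% model$coef))
  matrix(clamp(pr, 1e-6, 1 - 1e-6), nrow = length(A))
}

#' Draw reference-free simulation parameters
#'
#' Generates gene-level ZTNB parameters and cell depths for simulation when
#' no reference count matrix is supplied: rates `lambda_j` log-normal with
#' median 1e-4 per unit depth and log-sd 1.5, dispersions `phi_j ~
#' Gamma(shape 2, scale 1)`, depths `N_i` log-normal around 1e6 total
#' counts, and a [dropout_surface()] with a negative expression slope.
#'
#' @param p number of genes (default 10000).
#' @param n_cells number of cells (default 174).
#' @param lambda_meanlog,lambda_sdlog log-normal parameters of the rates.
#' @param phi_shape,phi_scale gamma parameters of the dispersions.
#' @param depth_meanlog,depth_sdlog log-normal parameters of the depths.
#' @param dropout a `dropout_surface` (or `dropout_fit`).
#' @return List with `params` (`data.frame` of `lambda`, `phi`), `depths`,
#'   and `dropout`.
#' @export
reference_free_params <- function(p = 10000, n_cells = 174,
                                  lambda_meanlog = log(1e-4),
                                  lambda_sdlog = 1.5,
                                  phi_shape = 2, phi_scale = 1,
                                  depth_meanlog = log(1e6),
                                  depth_sdlog = 0.25,
                                  dropout = dropout_surface()) {
  list(params = data.frame(lambda = rlnorm(p, lambda_meanlog, lambda_sdlog),
                           phi = pmax(rgamma(p, shape = phi_shape,
                                             scale = phi_scale), 0.05)),
       depths = rlnorm(n_cells, depth_meanlog, depth_sdlog),
       dropout = dropout)
}

#' Assign ground-truth DE status and effect sizes
#'
#' Membership `a` marks `round(cr * p)` uniformly chosen genes; each gene is
#' DE with probability `plogis(tau0 + a_j tau1)`; DE effect sizes are drawn
#' `N(0, effect_sd^2)` (default sd 3.5) and fold changes are their
#' exponential.
#'
#' @param p number of genes.
#' @param cr gene set coverage rate in (0, 1).
#' @param tau0,tau1 logistic DE-assignment parameters.
#' @param effect_sd standard deviation of DE effect sizes (default 3.5).
#' @return A `data.frame` of class `sim_truth` with columns `a`,
#'   `gamma_true`, `beta_true`, `fc`, plus attributes `tau` and `effect_sd`.
#' @export
assign_truth <- function(p, cr, tau0, tau1 = 0, effect_sd = 3.5) {
  stopifnot(cr > 0, cr < 1)
  a <- integer(p)
  a[sample.int(p, round(cr * p))] <- 1L
  gamma <- rbinom(p, 1, prior_pi(tau0, tau1, a))
  beta <- ifelse(gamma == 1, rnorm(p, 0, effect_sd), 0)
  out <- data.frame(a = a, gamma_true = gamma, beta_true = beta,
                    fc = exp(beta))
  attr(out, "tau") <- c(tau0 = tau0, tau1 = tau1)
  attr(out, "effect_sd") <- effect_sd
  class(out) <- c("sim_truth", "data.frame")
  out
}

#' Simulate two-group scRNA-seq counts from the ZTNB model
#'
#' Cells in group 1 have gene means `lambda_j * fc_j * N_i`, cells in group
#' 2 `lambda_j * N_i`; counts are NB draws with gene dispersion `phi_j`,
#' then set to zero with the cell- and gene-specific dropout probability.
#'
#' @param params `data.frame` with `lambda` and `phi` per gene.
#' @param dropout a dropout model for [predict_dropout()], or `NULL` for no
#'   dropout.
#' @param truth a `sim_truth` from [assign_truth()].
#' @param group_sizes integer `(n1, n2)` (default `c(105, 69)`).
#' @param depths per-cell totals `N_i`; drawn log-normal around 1e6 when
#'   missing.
#' @return List with `counts` (genes x cells), `labels` (1/2 per cell),
#'   `depths`, and `truth`.
#' @export
simulate_counts <- function(params, dropout, truth,
                            group_sizes = c(105, 69), depths = NULL) {
  p <- nrow(params)
  stopifnot(nrow(truth) == p)
  n <- sum(group_sizes)
  if (is.null(depths)) depths <- rlnorm(n, log(1e6), 0.25)
  stopifnot(length(depths) == n)
  labels <- rep(1:2, times = group_sizes)
  lam_mat <- outer(params$lambda, depths)  # baseline mean per cell
  lam_mat[, labels == 1] <- lam_mat[, labels == 1] * truth$fc
  counts <- matrix(rnbinom(p * n, mu = lam_mat,
                           size = rep(params$phi, times = n)),
                   nrow = p)
  if (!is.null(dropout)) {
    # dropout depends on the gene's expression level; evaluate per group so
    # the genes x cells probability matrix reflects the fold change
    pz <- matrix(NA_real_, p, n)
    for (g in 1:2) {
      cells <- which(labels == g)
      lam_g <- if (g == 1) params$lambda * truth$fc else params$lambda
      pz[, cells] <- predict_dropout(dropout, lam_g, depths[cells])
    }
    counts[runif(p * n) < pz] <- 0L
  }
  list(counts = counts, labels = labels, depths = depths, truth = truth)
}

#' Median-of-ratios size factors
#'
#' Robust per-cell normalization factors: the median across genes of the
#' ratio of each cell's count to the gene's geometric mean, computed over
#' genes with no zero counts (falling back to positive-count geometric means
#' when fewer than `min_genes` zero-free genes exist). Robust to composition
#' bias from a few very large fold changes, unlike raw library totals.
#'
#' @param counts genes x cells count matrix.
#' @param min_genes minimum number of zero-free genes before falling back.
#' @return Per-cell size factors with geometric mean 1.
#' @export
size_factors <- function(counts, min_genes = 20) {
  lg <- log(counts)
  zero_free <- rowSums(!is.finite(lg)) == 0
  if (sum(zero_free) >= min_genes) {
    sub <- lg[zero_free, , drop = FALSE]
    ref <- rowMeans(sub)
    sf <- apply(sub - ref, 2, median)
  } else {
    lg[!is.finite(lg)] <- NA
    ref <- rowMeans(lg, na.rm = TRUE)
    keep <- is.finite(ref)
    sf <- apply(lg[keep, , drop = FALSE] - ref[keep], 2,
                median, na.rm = TRUE)
  }
  sf <- exp(sf - mean(sf))
  sf
}

#' Internal negative binomial Wald DE test
#'
#' Per gene, fits the NB log-linear model `log mu = log N_i + b0 + b1 *
#' 1(group 1)` with per-gene maximum-likelihood dispersion (method-of-moments
#' fallback) and performs a Wald test on the group coefficient. Genes whose
#' joint fit does not converge get a score-test fallback and are flagged;
#' all-zero genes are excluded.
#'
#' @param counts genes x cells count matrix.
#' @param labels per-cell group labels (1/2); the coefficient is the log
#'   fold change of group 1 over group 2.
#' @param depths per-cell offsets `N_i`; by default median-of-ratios size
#'   factors ([size_factors()]) scaled to the geometric mean library size,
#'   which protects the offset from composition bias. Pass known depths to
#'   override.
#' @param gene_id optional identifiers (default `gene1..geneP`).
#' @return A summary-statistics `data.frame` (`gene_id`, `beta_hat`, `se`,
#'   `z`, `p`) with extra columns `phi` and `flag` (0 converged, 1 fallback,
#'   2 excluded); excluded genes carry `NA` statistics.
#' @export
internal_de_test <- function(counts, labels, depths = NULL,
                             gene_id = paste0("gene", seq_len(nrow(counts)))) {
  if (is.null(depths))
    depths <- size_factors(counts) * exp(mean(log(pmax(colSums(counts), 1))))
  stopifnot(length(labels) == ncol(counts), all(labels %in% 1:2))
  if (sum(labels == 1) < 2 || sum(labels == 2) < 2)
    stop("both groups need at least 2 cells")
  res <- nb_wald_cpp(t(counts), as.integer(labels == 1), log(depths),
                     max_outer = 8L, tol = 1e-4)
  out <- data.frame(gene_id = gene_id, beta_hat = res$beta, se = res$se,
                    z = res$z, p = res$p, phi = res$phi, flag = res$flag,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(res$flag == 2L)
  out
}

#' Simulate summary statistics directly from the mixture model
#'
#' Count-free generation conditioned on the truth labels: `z_j ~ N(0,
#' sigma_beta2 + 1)` for DE genes and `N(0, 1)` otherwise, with `beta_hat =
#' z * se`.
#'
#' @param truth a `sim_truth`.
#' @param se standard errors (scalar or vector; default 1).
#' @param sigma_beta2 slab variance scaling factor.
#' @return A summary-statistics `data.frame`.
#' @export
simulate_summary_stats <- function(truth, se = 1, sigma_beta2) {
  p <- nrow(truth)
  se <- rep(se, length.out = p)
  sd_z <- ifelse(truth$gamma_true == 1, sqrt(sigma_beta2 + 1), 1)
  z <- rnorm(p, 0, sd_z)
  data.frame(gene_id = paste0("gene", seq_len(p)), beta_hat = z * se,
             se = se, z = z, p = 2 * pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Write simulated counts and truth to plain-text files
#'
#' Counts go to MatrixMarket sparse format (`.mtx`) with gene and cell TSVs,
#' truth to a TSV with columns `gene_id`, `a`, `gamma`, `beta`, `fc`.
#'
#' @param sim output of [simulate_counts()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(sim$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  write.table(data.frame(gene_id = paste0("gene", seq_len(nrow(sim$counts)))),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(cell_id = paste0("cell", seq_len(ncol(sim$counts))),
                         group = sim$labels, depth = sim$depths),
              file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- sim$truth
  write.table(data.frame(gene_id = paste0("gene", seq_len(nrow(tr))),
                         a = tr$a, gamma = tr$gamma_true, beta = tr$beta_true,
                         fc = tr$fc),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
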