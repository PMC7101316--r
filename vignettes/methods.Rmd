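---
title: "Joint differential expression and gene set enrichment from summary statistics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint differential expression and gene set enrichment from summary statistics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssenrich)
```

## The problem

Differential expression (DE) analysis in single-cell RNA sequencing tests one
gene at a time and, because the data are shallow and noisy, tends to be
underpowered and unstable across DE tools. Gene set enrichment (GSE) analysis
is usually bolted on afterwards, discarding the feedback that an enriched
pathway provides about which of its member genes are likely DE. `ssenrich`
implements a hierarchical Bayesian model that performs the two tasks jointly,
using only gene-level DE summary statistics — an effect size estimate
$\hat\beta_j$ and its standard error $\mathrm{se}(\hat\beta_j)$ for each of
$p$ genes — plus a binary gene set membership vector $a$.

## The model

The observed effect size is assumed to centre on the true effect,
$\hat\beta_j \sim N(\beta_j, \mathrm{se}(\hat\beta_j)^2)$, and the true
effect follows a spike-and-slab mixture

$$\beta_j \sim \pi_j\, N(0,\, \mathrm{se}(\hat\beta_j)^2\sigma_\beta^2)
  + (1-\pi_j)\,\delta_0 ,$$

where $\delta_0$ is a point mass at zero (non-DE genes have exactly zero
effect), and $\sigma_\beta^2$ scales the slab. Scaling the slab by the
squared standard error makes the analysis invariant to the scale on which
effects are reported, and is equivalent to the marginal z-score model

$$z_j \sim \pi_j\, N(0, \sigma_\beta^2 + 1) + (1-\pi_j)\, N(0, 1),$$

which is the canonical internal representation: `(beta_hat, se)` inputs are
converted to $z = \hat\beta/\mathrm{se}$ on ingestion. The prior DE
probability depends on gene set membership through a logistic model,

$$\mathrm{logit}(\pi_j) = \tau_0 + a_j \tau_1 ,$$

so $\tau_0$ sets the baseline fraction of DE genes ($\tau_0 = -2$
corresponds to roughly 12% DE genes, $\tau_0 = -3$ to about 4.7%) and
$\tau_1$ is the log odds ratio of DE inside versus outside the set. The GSE
test is the Wald test of $H_0 : \tau_1 = 0$; the DE output is the posterior
inclusion probability (PIP) $P(\gamma_j = 1 \mid \text{data})$ of each
gene's latent DE indicator $\gamma_j \sim \mathrm{Bern}(\pi_j)$.

The slab scale carries a conjugate inverse-gamma prior
$\sigma_\beta^2 \sim \mathrm{InvG}(a_\beta = 3, b_\beta = 20)$, giving prior
mean $b_\beta/(a_\beta - 1) = 10$; $a_\beta > 2$ guarantees a finite prior
variance. A model variant (`variant = "unscaled"`) removes the dependence of
the prior on the standard errors: $\beta_j \sim \pi_j N(0, \sigma_\beta^2) +
(1-\pi_j)\delta_0$, so $\hat\beta_j \mid \gamma_j = 1 \sim N(0,
\mathrm{se}_j^2 + \sigma_\beta^2)$. The two variants share all machinery and
differ only in the per-gene slab variance.

## Inference: EM with a Gibbs E-step

`fit_gene_set()` treats $(\gamma, \beta)$ as missing data and alternates:

* **E-step** (`e_step()`): a systematic-scan Gibbs sampler. Per sweep,
  (i) $\gamma_j$ is drawn from its full conditional with $\beta_j$
  integrated out — Bernoulli with odds $\frac{\pi_j}{1-\pi_j}\,
  \frac{N(z_j;0,\sigma_\beta^2+1)}{N(z_j;0,1)}$; (ii) for included genes
  the standardized effect is drawn from
  $N\!\big(z_j\sigma_\beta^2/(\sigma_\beta^2+1),\,
  \sigma_\beta^2/(\sigma_\beta^2+1)\big)$; (iii) $\sigma_\beta^2$ is drawn
  conjugately from $\mathrm{InvG}(a_\beta + \tfrac12\sum\gamma_j,\,
  b_\beta + \tfrac12\sum\gamma_j \tilde\beta_j^2)$. These conditionals
  follow from the model by standard conjugate algebra. PIPs are post-burn-in
  averages of $\gamma_j$; the per-sweep complete-data scores
  $S(\tau) = \sum_j x_j(\gamma_j - \pi_j)$, $x_j = (1, a_j)^\top$, are
  retained for the information correction below.
* **M-step** (`m_step()`): maximizing the expected complete-data
  log-likelihood in $\tau$ is exactly a logistic regression of the PIPs on
  the membership indicator, solved by iteratively reweighted least squares
  (gradient norm $< 10^{-8}$). Under perfect separation the coefficients
  are clamped at $\pm 25$ and flagged. $\sigma_\beta^2$ is carried between
  iterations as its E-step posterior mean; the M-step touches only $\tau$.

Iteration stops when $\max|\Delta\tau|$ falls below `em_tol` (default
$10^{-3}$) or after `em_max_iter` iterations. With soft PIPs the Monte Carlo
noise of the $\tau$ update (order $10^{-2}$ at typical study sizes) exceeds
the default tolerance; such fits run to the iteration cap and report
`converged = FALSE` while still delivering estimates whose quality is
governed by the chain length, as the calibration suite verifies. The
trajectory of the observed-data log-likelihood is returned for monotonicity
diagnostics.

**Initialization.** $\tau_0 = \mathrm{logit}(\text{fraction of genes with
input } p < 0.05)$ clamped to $[-5, -0.5]$; $\tau_1 = 0$;
$\sigma_\beta^2$ at its prior mean 10. These match the prior structure and
avoid favouring enrichment a priori.

**Standard errors and the enrichment p-value.** Naive complete-data standard
errors for $\tau_1$ ignore the uncertainty in $\gamma$ and are anticonservative.
The observed information is corrected as $I_{\mathrm{obs}} =
I_{\mathrm{com}} - I_{\mathrm{mis}}$, where $I_{\mathrm{com}} = \sum_j x_j
x_j^\top \pi_j(1-\pi_j)$ at $\hat\tau$ and $I_{\mathrm{mis}}$ is the
*empirical covariance of the per-sweep score vectors* rather than the
independence closed form $\sum_j x_jx_j^\top \mathrm{pip}_j(1-\mathrm{pip}_j)$
— the sampled slab variance induces posterior dependence across genes, which
the empirical covariance captures (the two agree when $\sigma_\beta^2$ is
held fixed, a property the test suite checks). The Wald statistic
$\hat\tau_1^2 / \widehat{\mathrm{Var}}(\hat\tau_1)$ is referred to
$\chi^2_1$. If $I_{\mathrm{obs}}$ is not positive definite, a ridge of
$10^{-6}\times$ trace is added and the fit flagged.

## Numerical choices

* All mixture computations run in log space with log-sum-exp; mixing
  probabilities are clamped to $[10^{-8}, 1-10^{-8}]$ inside likelihoods so
  the objective stays finite under separation (fits on rare, imbalanced
  sets — e.g. baseline log-odds $\le -3$ with 1% coverage — degrade to
  flagged, clamped estimates rather than erroring).
* Input p-values are clamped at $10^{-300}$ before the normal quantile
  transform; genes whose completed standard error would be 0 or non-finite
  are excluded with a reported count, not imputed.
* `read_summary_stats()` exposes an optional `max_p` filter that removes
  genes whose input p-value exceeds a cutoff. Some upstream DE tools emit
  null p-values that pile up near 1 rather than spreading uniformly, which
  distorts the mixture fit; because the phenomenon is tool- and data-set
  specific the filter is off by default and left to the analyst's judgement.
* The Gibbs E-step is compiled code. Intermediate EM iterations may use a
  shorter chain than the final E-step (`warmup_sweeps`/`warmup_burn_in`), a
  standard Monte Carlo EM economy: only $\sigma_\beta^2$ persists across
  sweeps and its chain mixes in tens of sweeps, so short warmup chains
  suffice for $\tau$ updates while the final chain determines the PIPs and
  score samples. Package defaults are 1000 sweeps with 500 burn-in
  throughout; the study drivers use 500 sweeps (100 burn-in) with 200-sweep
  warmup E-steps, which leaves null calibration and interval coverage
  intact at a fraction of the cost.
* Per-set seeds in `run_gse_scan()` are a stable hash of (master seed, set
  name), so adding or removing sets never perturbs other sets' results, and
  a fixed seed makes every fit bitwise reproducible.
* Ranking ties (DE calls, power curves) are broken by stable input order.

## The simulator

`assign_truth()`, `simulate_counts()` and `internal_de_test()` reproduce a
two-group scRNA-seq simulation design: DE status is assigned by the logistic
model above; DE effect sizes are $N(0, 3.5^2)$ on the log scale with fold
change $e^{\beta_j}$; counts for 174 cells (105 versus 69 by default) are
drawn per gene from a negative binomial with mean $\lambda_j\,
\mathrm{fc}_j\, N_i$ in one group and $\lambda_j N_i$ in the other, then set
to zero with a cell- and gene-specific dropout probability.

Two parameter sources are supported:

* **Reference mode**: `ztnb_mom_estimate()` recovers gene-level
  $(\lambda_j, \phi_j)$ from a user-supplied count matrix by iterating the
  zero-truncation-corrected method-of-moments updates over nonzero counts,
  and `fit_dropout_model()` fits the dropout surface
  $\mathrm{logit}(p_{ij}) = s(A_j) + \log N_i + s(A_j)\log N_i$ with a
  5-degree-of-freedom cubic B-spline $s(\cdot)$ in the gene's average log2
  CPM (the smoother's dimension is a package choice, exposed in the
  configuration). The moment iteration is consistent at its fixed point but
  can diverge for heavily truncated genes (mean counts near 1); divergent
  genes fall back to plain moments on the nonzero counts and are flagged.
* **Reference-free mode** (`reference_free_params()`, the default in tests):
  $\lambda_j \sim \mathrm{lognormal}(\log 10^{-4}, 1.5^2)$ per-depth rates,
  $\phi_j \sim \mathrm{Gamma}(2, \text{scale } 1)$, depths
  $N_i \sim \mathrm{lognormal}$ around $10^6$, and a parametric dropout
  surface $\mathrm{logit}(p_{ij}) = 1.5 - \log_{10}(\lambda_j \cdot 10^6 +
  1) - 0.5(\log N_i - \log 10^6)$. The intercept and slopes were chosen
  once to give zero fractions (about 40% overall, higher for lowly
  expressed genes) and depth dependence typical of plate-based scRNA-seq.

The internal DE stage is a gene-wise negative binomial log-linear Wald test
with a log-offset, per-gene maximum-likelihood dispersion (Newton on
$\log\phi$, method-of-moments fallback) and a score-test fallback for
non-converged genes; it matches `MASS::glm.nb` to $10^{-6}$ on shared
fixtures. Its offset defaults to median-of-ratios size factors rather than
raw library totals: with effect-size sd 3.5 a handful of enormous fold
changes dominates one group's totals, and a raw total-count offset shifts
every null gene (genomic control factors in the hundreds); median-of-ratios
normalization removes this composition bias. Because the test is a plain NB
model, dropout zeros are absorbed as extra dispersion, making the gene-level
p-values conservative on dropout-bearing data; this affects neither the
validity of the enrichment test nor the DE ranking, and the calibration
suite checks both levels.

**What the simulator does and does not emulate.** Simulated data match the
generating ZTNB/dropout model by construction — zero fractions, mean–variance
relationships, depth effects. They do not contain batch structure, gene–gene
correlation, cell-type misassignment, or the post-selection effects of
clustering-derived labels; passing tests on simulated data therefore
demonstrate correctness of the method's own machinery and its behaviour
under its stated assumptions, not robustness to every artefact of real data.

## Evaluation protocol

* **Power at fixed FDR** (`power_at_fdr()`): with known truth, the largest
  call set whose realized false discovery proportion is at or below the
  target; with permutation nulls, thresholding by the empirical FDR
  $\widehat{\mathrm{FDR}}(t) = \frac{\#\{\text{null } p \le t\}/n_{\mathrm{perm}}}
  {\max(1, \#\{\text{observed } p \le t\})}$, monotonized by a cumulative
  minimum from the largest threshold (the step-down details are a package
  choice).
* **Permutations** (`permute_set_labels()`): the default mode applies one
  gene relabeling jointly to all sets, preserving every pairwise overlap
  exactly so that correlations between overlapping sets are comparable
  between real and permuted data; an independent per-set mode is also
  provided. Ten permutations is the conventional default.
* **DE permutation nulls** (`de_permutation_null()`): cell labels are
  shuffled, the DE stage rerun, and a single E-step executed with $\hat\tau$
  frozen at the unpermuted estimates. Re-estimating $\tau$ on permuted data
  adapts to noise and deflates the null PIP pool, which understates the
  empirical FDR — the frozen-$\tau$ protocol avoids that, and the test suite
  asserts the ordering.
* **Genomic control** (`genomic_control_lambda()`): median of the
  $\chi^2_1$-transformed p-values divided by $\mathrm{qchisq}(0.5, 1) =
  0.4549364$. Note that this median-based factor is a noisy statistic: even
  perfectly uniform p-values give $\lambda_{gc} \approx 1 \pm 0.13$ at 300
  fits, which is why the calibration study defaults to 2000 fits.
* **Bayesian FDR** (`bayesian_fdr()`): genes sorted by PIP; the expected FDR
  of the top-$k$ set is the mean of $1-\mathrm{pip}$ over it; calls are the
  largest set meeting the target. The estimator (direct posterior expected
  FDR) is a package choice.
* **Model averaging** (`bma_pip()`): without a pre-selected annotation,
  per-set PIPs are combined with weights proportional to a BIC-style
  evidence approximation from each set's final observed-data log-likelihood
  (3 free parameters), with a uniform-weights fallback; the exact weighting
  of the original formulation not being available, BIC weighting is the
  package's default choice.
* `jaccard_topk()` and `roc_auc()` quantify cross-method consistency and
  ranking quality.

## Study drivers and problem sizes

The packaged studies size their simulations for a single CPU while keeping
the scientific conditions fixed:

* `gse_power_study()`: 100 enriched ($\tau_1 = 0.5$) and 400 null replicates
  of 10,000 genes $\times$ 174 cells with the full count-level pipeline —
  the package's desk-scale version of the enrichment power experiment
  (baseline $\tau_0 = -2$, coverage 10%, power read at 5% FDR).
* `null_calibration_study()`: 2000 model-simulated null fits of 2000 genes
  in the signal regime of the count-level design (slab variance
  $(3.5/0.3)^2$, i.e. effect sd 3.5 seen through standard errors of about
  0.3). In much weaker-signal regimes the Wald statistic's null median sits
  visibly below the $\chi^2_1$ median at desk-scale gene counts — a
  finite-sample property of the test, shared by the exact maximizer of the
  marginal likelihood — so calibration is assessed where the simulation
  design actually operates.
* `recovery_study()`: 50 replicates of 10,000 genes at
  $\tau = (-2, 1)$, $\sigma_\beta^2 = 9$, reporting the mean enrichment
  estimate and 95% Wald interval coverage.
* `fdr_calibration_study()`: 50 replicates of 2000 genes, realized false
  discovery proportion of PIP calls at a nominal 5% Bayesian FDR.
* `sensitivity_scan()`: refits one set across slab prior means 0.001, 0.1,
  1, 10, 100 (shape fixed at 3).

## Known limitations

* One gene set is modelled at a time (composite likelihood); overlapping
  sets are handled through the permutation protocol, not joint modelling.
* Identifiability degrades for very rare, imbalanced configurations
  (baseline DE fraction below ~5% combined with ~1% coverage); the package
  returns clamped, flagged estimates there by design.
* The gene-level NB Wald stage is deliberately simple; when pairing the
  enrichment model with real data, any well-calibrated external DE tool's
  summary statistics can (and should) be supplied instead.
* Gene matching is exact and case-sensitive; no identifier aliasing.
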