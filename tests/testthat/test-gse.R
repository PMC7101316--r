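test_that("label permutations preserve set sizes and are reproducible", {
  universe <- paste0("g", 1:100)
  coll <- gene_set_collection(universe, list(A = universe[1:10],
                                             B = universe[5:40]))
  for (mode in c("joint", "per_set")) {
    perms <- permute_set_labels(coll, n_perm = 10, mode = mode, seed = 42)
    expect_length(perms, 10)
    for (pc in perms) expect_equal(set_sizes(pc), set_sizes(coll))
    again <- permute_set_labels(coll, n_perm = 10, mode = mode, seed = 42)
    expect_identical(perms, again)
  }
  # joint relabeling preserves pairwise overlaps exactly
  perms <- permute_set_labels(coll, n_perm = 5, mode = "joint", seed = 1)
  ov <- function(cc) length(intersect(cc$sets$A, cc$sets$B))
  expect_true(all(vapply(perms, ov, numeric(1)) == ov(coll)))
})

test_that("empirical FDR matches hand enumeration and is monotone", {
  # one permutation: null pool (0.2, 0.9), observed (0.001, 0.5)
  fdr <- empirical_fdr(c(0.001, 0.5), c(0.2, 0.9), n_perm = 1)
  expect_equal(fdr, c(0, 0.5))
  expect_error(empirical_fdr(0.5, numeric(0), 1), "empty")
  # null self-comparison gives FDR near 1
  set.seed(2)
  obs <- runif(200)
  nul <- runif(2000)
  fdr2 <- empirical_fdr(obs, nul, n_perm = 10)
  expect_gt(median(fdr2), 0.7)
  expect_true(all(fdr2 >= 0 & fdr2 <= 1))
  # monotone non-increasing in the p-value threshold
  ord <- order(obs)
  expect_true(all(diff(fdr2[ord]) >= -1e-12))
})

test_that("genomic control factor is 1 for p = 0.5 and for uniform p-values", {
  expect_equal(genomic_control_lambda(rep(0.5, 5)), 1)
  set.seed(3)
  expect_equal(genomic_control_lambda(runif(10000)), 1, tolerance = 0.03)
  # deflation and inflation move the factor in the right direction
  set.seed(3)
  expect_lt(genomic_control_lambda(runif(1000, 0.3, 1)), 1)
  expect_gt(genomic_control_lambda(runif(1000, 0, 0.2)), 1)
  expect_error(genomic_control_lambda(numeric(0)), "empty")
})

test_that("hypergeometric test: exact tail values and the no-DE boundary", {
  st <- gene_stats(paste0("g", 1:20), p = rep(0.5, 20), sign = 1)
  expect_equal(hypergeometric_gse(st, c(rep(1, 5), rep(0, 15))), 1)
  # all 5 DE genes inside a 5-gene set out of 20
  st2 <- gene_stats(paste0("g", 1:20),
                    p = c(rep(0.01, 5), rep(0.5, 15)),
                    sign = 1)
  expect_equal(hypergeometric_gse(st2, c(rep(1, 5), rep(0, 15))),
               1 / choose(20, 5))
})

test_that("scan results are independent of set order and of other sets", {
  dat <- sim_model_data(400, tau1 = 1, cr = 0.1, seed = 18)
  universe <- dat$stats$gene_id
  setA <- universe[dat$truth$a == 1]
  setB <- universe[301:360]
  collAB <- gene_set_collection(universe, list(A = setA, B = setB))
  collBA <- gene_set_collection(universe, list(B = setB, A = setA))
  collA <- gene_set_collection(universe, list(A = setA))
  cfg <- quick_config(seed = 99)
  sAB <- run_gse_scan(dat$stats, collAB, config = cfg)
  sBA <- run_gse_scan(dat$stats, collBA, config = cfg)
  sA <- run_gse_scan(dat$stats, collA, config = cfg)
  expect_equal(sAB$table[sAB$table$set_name == "A", ],
               sBA$table[sBA$table$set_name == "A", ],
               ignore_attr = TRUE)
  expect_identical(sAB$results$A$pip, sA$results$A$pip)
  expect_identical(sAB$results$A$p_value, sA$results$A$p_value)
  # a single-set scan is just fit_gene_set
  direct <- fit_gene_set(dat$stats$z, dat$stats$se,
                         set_membership(collA, "A"),
                         config = mcmc_config(400, 100,
                                              seed = derive_seed(99, "A"),
                                              em_max_iter = 10,
                                              warmup_sweeps = 200,
                                              warmup_burn_in = 50))
  expect_identical(sA$results$A$p_value, direct$p_value)
})

test_that("permutation scan attaches an empirical FDR column", {
  dat <- sim_model_data(300, tau1 = 2, cr = 0.15, seed = 44)
  universe <- dat$stats$gene_id
  coll <- gene_set_collection(universe,
                              list(S = universe[dat$truth$a == 1]))
  scan <- run_gse_scan(dat$stats, coll, config = quick_config(seed = 7),
                       n_perm = 3)
  expect_true("empirical_fdr" %in% names(scan$table))
  expect_length(scan$null_p, 3)
  expect_true(all(scan$table$empirical_fdr >= 0 &
                    scan$table$empirical_fdr <= 1))
})
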