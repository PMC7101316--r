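# Shared in-code fixtures for the test suite.

# small summary-statistics file on disk
write_stats_fixture <- function(path, df) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small GMT file on disk
write_gmt_fixture <- function(path, lines) {
  writeLines(lines, path)
  path
}

# model-simulated summary statistics + truth under a fixed seed
sim_model_data <- function(p, tau0 = -2, tau1 = 0, cr = 0.1,
                           sigma_beta2 = 9, seed = 1) {
  set.seed(seed)
  truth <- assign_truth(p, cr, tau0, tau1)
  list(truth = truth,
       stats = simulate_summary_stats(truth, se = 1,
                                      sigma_beta2 = sigma_beta2))
}

# light MCMC configuration for fast unit-level fits
quick_config <- function(seed = NULL, em_max_iter = 10) {
  mcmc_config(n_sweeps = 400, burn_in = 100, seed = seed,
              em_max_iter = em_max_iter,
              warmup_sweeps = 200, warmup_burn_in = 50)
}
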