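# Shared fixtures: one small clean simulated run (12 trials) reused across
# test files, a fast ICA configuration for multi-fit tests, and unit
# Laplacian sources for separation oracles.

fast_ica <- ica_config(max_iter = 128)

fix_cfg <- run_config(seed = 42, ica = fast_ica)
fix_sim <- generate_dataset(sim_config(n_trials_per_class = 4, seed = 42))
fix_trials <- preprocess_recording(fix_sim$recording, fix_cfg)

# unit-variance Laplacian sources (super-Gaussian)
laplacian_sources <- function(n, T) {
  matrix(stats::rexp(n * T) * sign(stats::runif(n * T) - 0.5) / sqrt(2),
         nrow = n)
}

# random mixing matrix with bounded condition number
random_mixing <- function(n, max_kappa = 10) {
  repeat {
    A <- matrix(stats::rnorm(n * n), n)
    if (kappa(A, exact = TRUE) < max_kappa) return(A)
  }
}

nine_labels <- channel_scheme("nine")$labels
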