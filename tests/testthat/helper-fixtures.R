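# Shared fixtures. MCMC-based tests use reduced sampler sizes; the shared
# simulation is built once per test run.

fast_spec3 <- function(seed = 1, n = 800, chains = 2)
  hbm_spec(3, n_chains = chains, n_warmup = n, n_samples = n,
           n_adapt = 200, seed = seed)

fast_spec4 <- function(seed = 1, n = 600, chains = 2)
  hbm_spec(4, n_chains = chains, n_warmup = n, n_samples = n,
           n_adapt = 200, seed = seed)

# Condition summaries built directly from the DoG curve (no simulation):
# P participants x report types, ten bins, Gaussian bin noise.
noiseless_summaries <- function(alphas = c(perceptual = -0.8,
                                           consolidation = 1.6,
                                           retrieval = 6.2),
                                n_participants = 3, w = 0.02, beta = 0,
                                noise_sd = 0, seed = 1) {
  set.seed(seed)
  bins <- c(seq(-144, 144, by = 36), 180)
  out <- expand.grid(participant = sprintf("P%02d",
                                           seq_len(n_participants)),
                     report_type = names(alphas), bin_center = bins,
                     stringsAsFactors = FALSE)
  out$mean_error <- dog(out$bin_center, alphas[out$report_type], w, beta) +
    rnorm(nrow(out), 0, noise_sd)
  out$n <- 30L
  out
}

.fixture_env <- new.env()

# One moderate simulated experiment with trajectories, shared across tests.
shared_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_experiment(
      sim_config(n_participants = 3, n_perceptual_trials = 40,
                 n_wm_trials = 60, seed = 42))
  .fixture_env$sim
}

shared_stats <- function() {
  if (is.null(.fixture_env$stats))
    .fixture_env$stats <- preprocess_trajectories(shared_sim()$trajectories)
  .fixture_env$stats
}
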