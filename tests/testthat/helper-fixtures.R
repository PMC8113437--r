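# Shared fixtures: a contaminated-area environment term and quick generators.

default_env <- function() environment_spec(log(1e6), log(1e6))

true_params <- function() c(Q = -4.851, mu = 0.173, A = 0.641, P = 0.405)

# small clean synthetic record set (no censoring kept, no outliers)
quick_records <- function(n = 300, seed = 1, noise_sd = 1, ...) {
  cfg <- simulation_config(n_samples = n, seed = seed,
                           noise_sd_by_district = noise_sd, ...)
  g <- generate_fukushima(cfg)
  g$records[!g$records$below_detection, , drop = FALSE]
}

# records drawn from random (but plausible) model parameters; returns truth
random_fixture <- function(seed, n = 150) {
  with_seed(seed * 7919, {
    tr <- model_parameters(q = runif(1, -7, -3), mu = runif(1, 0.02, 0.4),
                           nu = 1, amp = runif(1, 0.1, 1.2),
                           phase = runif(1, 0, 1))
    list(records = generate_fukushima(simulation_config(
      truth = tr, n_samples = n, seed = seed,
      noise_sd_by_district = runif(1, 0.3, 1.2)))$records,
      truth = tr)
  })
}

with_seed <- radcesium:::with_seed
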