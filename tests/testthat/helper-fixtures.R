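# Shared fixtures: all inputs are generated in code at test time.

# A small, fast engine configuration: 8 theta cycles at 8 Hz.
fast_engine <- function(...) {
  engine_params(duration_ms = 1000, ...)
}

# Deterministic pseudo-Poisson 0/1 spike train.
poisson_train <- function(n_steps, rate_per_step, seed = 42) {
  set.seed(seed)
  as.integer(runif(n_steps) < rate_per_step)
}

# Truncated-kernel convolution oracle: contribution of each past spike,
# aged through an exponential kernel that expires after `length` steps.
conv_oracle <- function(spikes, weight, tau, length, dt = 1) {
  n <- length(spikes)
  out <- numeric(n)
  for (t in seq_len(n)) {
    ages <- 0:(min(t - 1, length - 1))
    out[t] <- sum(weight * spikes[t - ages] * exp(-ages * dt / tau))
  }
  out
}

small_trial_design <- function(seed = 7, ...) {
  trial_design(master_seed = seed, n_patients = 4,
               cohort = cohort_spec(n_networks = 12),
               engine = fast_engine(), ...)
}
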