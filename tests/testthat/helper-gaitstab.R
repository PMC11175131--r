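# shared fixtures: tiny deterministic profiles and trials built in code

test_profile <- function(seed = 1, noise_scale = 0.05) {
  p <- sample_failure_counts(cohort_spec(n_participants = 1, environments = "A",
                                         seed = seed,
                                         environment_presets = list(A = environment_preset("A"))))[1, ]
  p$noise_scale <- noise_scale
  p
}

# a reference gait cycle for one profile (unfatigued, non-obstacle)
test_reference <- function(profile, seed = 2) {
  reference_from_trial(
    synth_trial(profile, environment_preset("A"), level = 0, seed = seed)$trace)
}

# independent Pearson oracle: plain covariance / variance arithmetic
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  sxy / sqrt(sxx * syy)
}
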