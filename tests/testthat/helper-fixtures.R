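# small session builders shared across test files

tiny_session <- function(stage = "T2", n_trials = 40, n_neurons = 12,
                         seed = 1, ...) {
  fx <- planted_effects(n_neurons = n_neurons, seed = seed, ...)
  simulate_session(stage_config(stage), n_trials, fx, seed = seed)
}

# a label-independent population: all planted gains zero
noise_effects <- function(n_neurons = 8, seed = 1) {
  planted_effects(
    n_neurons = n_neurons,
    frac_direction = 0, frac_speed = 0, frac_reward = 0, frac_expected = 0,
    seed = seed)
}

# AR(1) forward filter, used as an independent forward model in oracles
ar1_conv <- function(s, gamma) {
  as.numeric(stats::filter(s, gamma, method = "recursive"))
}
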