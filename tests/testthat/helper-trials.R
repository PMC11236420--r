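# Shared fixtures, built in code.

# one participant's trial table with constant confidence, inputs on the
# response scale
toy_trials <- function(seed = 1, n = 80, confidence = 0.8,
                       condition = make_condition("low", "low", n_trials = n)) {
  d <- make_trials(
    generate_sequence(condition, seed = seed),
    generate_schedule(condition$n_trials, seed = seed + 1),
    transform = input_transform(5, 15)
  )
  d$confidence <- confidence
  d
}

# memoised heavy fits shared between test files (computed at most once per
# test run)
fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fit_cache)) {
    assign(key, force(expr), envir = fit_cache)
  }
  get(key, envir = fit_cache)
}

# The reference synthetic study: responses simulated from the hierarchical
# expectation-weighted Kalman filter at moderate group-level parameters
# (12 subjects x 80 trials), refit with the same model at desk scale.
# Group spreads for s, epsilon and e0 are set to recovery-study width
# (comparable to the per-subject posterior uncertainty), so that the
# generating-vs-estimated correlation measures recoverability rather than
# shrinkage attenuation.
ekf_reference_config <- function() {
  cfg <- default_group_config("ekf")
  cfg$scale[cfg$name == "s"] <- 0.45
  cfg$scale[cfg$name == "epsilon"] <- 0.45
  cfg$scale[cfg$name == "e0"] <- 0.2
  cfg
}

ekf_reference_fit <- function() {
  cached("ekf_reference", {
    study <- simulate_study("ekf", n_subjects = 12, seed = 2024,
                            group_config = ekf_reference_config())
    fit <- sample_posterior(study$trials, "ekf",
                            fit_config(chains = 4, warmup = 1000,
                                       samples = 1000, seed = 77))
    list(study = study, fit = fit)
  })
}
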