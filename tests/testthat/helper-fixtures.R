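# Shared fixtures. Everything is generated in code; heavyweight study-scale
# objects are computed lazily once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

# small fast sampling grid for unit tests
sp_small <- function() sampling_spec(250, -1, 1)
# the study grid
sp_study <- function() sampling_spec(500, -2, 2)

tone <- function(f, sampling, amp = 1, phase = 0) {
  amp * cos(2 * pi * f * time_points(sampling) + phase)
}

# small simulator configuration for unit tests (reduced grid, fewer trials)
cfg_small <- function(n_trials = 20, rng_seed = 7, ...) {
  firefly_config(f_min = 0.5, f_max = 45, f_step = 0.5, n_trials = n_trials,
                 rng_seed = rng_seed, ...)
}

# Canonical study-scale Firefly/evoked discrimination experiment at the
# generator defaults (0.1-250 Hz grid at 0.1 Hz, 100 trials, 500 Hz,
# -2..+2 s), shared by the acceptance checks.
canonical_experiment <- function() {
  cached("canonical_experiment", function() {
    suppressWarnings(run_discrimination_experiment(firefly_config(rng_seed = 1)))
  })
}

# Canonical study-scale Firefly epoch set (same sub-seed rule as the
# experiment's firefly arm, so results line up).
canonical_firefly <- function() {
  cached("canonical_firefly", function() {
    cfg <- firefly_config(rng_seed = 1)
    cfg$rng_seed <- fireflyeeg:::derive_seed(1, 11)
    suppressWarnings(
      simulate_firefly(cfg, sampling = sp_study(), channels = "sim",
                       condition = "firefly"))
  })
}
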