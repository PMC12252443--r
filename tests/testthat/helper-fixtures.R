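# Small shared fixtures, built once per test run.

# Hourly noise-free curves: cheap, deterministic reference material.
hourly_curves_noisefree <- function(n = 3, seed = 101, duration_h = 336) {
  generate_dataset(n, seed = seed, duration_h = duration_h, step_min = 60,
                   noise = FALSE)
}

hourly_curves_noisy <- function(n = 3, seed = 101, duration_h = 336,
                                params = kinetic_params()) {
  generate_dataset(n, seed = seed, duration_h = duration_h, step_min = 60,
                   params = params)
}

# A tiny windowed dataset of short sinusoid-like curves for forecaster tests.
tiny_windows <- function(n_curves = 6, len = 60, nt = 16, pl = 8, seed = 5) {
  curves <- generate_dataset(n_curves, seed = seed,
                             duration_h = len, step_min = 60)
  make_windows(curves, nt = nt, pl = pl, stride = 4)
}

expect_within <- function(x, lo, hi) {
  expect_true(all(x >= lo & x <= hi),
              label = sprintf("values within [%g, %g]", lo, hi))
}
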