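# Independent oracles and small fixture factories used across the suite.

# Brute-force AUC: all-pairs count with ties worth 1/2.
auc_brute <- function(a, b) {
  mean(outer(b, a, function(x, y) (x > y) + 0.5 * (x == y)))
}

# OLS slope as the closed-form covariance/variance ratio.
ols_slope <- function(x, y) stats::cov(x, y) / stats::var(x)

# Compact synthetic session at the 2.5 kHz analysis rate.
tiny_session <- function(seed = 1, duration = 20,
                         grades = c("P120", "P600", "P1200"),
                         whiskers = c("gamma", "C2", "C4"),
                         spikes = TRUE, curvature = FALSE, ...) {
  gen_session(pad_model(sample_rate = 2500),
              if (spikes) neuron_model() else NULL,
              grades = grades, whiskers = whiskers,
              duration = duration, seed = seed, curvature = curvature, ...)
}
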