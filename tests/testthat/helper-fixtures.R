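# Shared fixtures, built in code at test time.

# full-window IRF (0-200 ns, 0.055 ns channels), as in the measurements
full_irf <- function() gaussian_irf()

# short-window IRF for cheap unit fits (0-44 ns)
short_irf <- function() gaussian_irf(n_channels = 800L)

registry <- photoacid_registry()

# 2N free in pH 7 buffer: the weak-photoacid reference configuration
cfg_2n_buffer <- registry[["2N"]]$buffer

# direct O(n^2) causal convolution (independent of the FFT route)
direct_convolve <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(k) sum(w[seq_len(k)] * x[k:1]), numeric(1))
}

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}

seeded_rnorm <- function(n, sd, seed) {
  set.seed(seed)
  rnorm(n, 0, sd)
}
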