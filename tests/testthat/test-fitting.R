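test_that("reduced chi-square behaves as a quadratic form", {
  model <- 1000 * exp(-(0:299) / 80) + 50
  expect_equal(chi2_reduced(model, model, 0), 0)
  obs <- round(model * 1.02)
  c1 <- chi2_reduced(model, obs, 0)
  c2 <- chi2_reduced(2 * model - obs, obs, 0)  # doubled residuals
  expect_equal(c2, 4 * c1, tolerance = 1e-6)
  expect_error(chi2_reduced(model, model[-1], 0),
               class = "photoacid_invalid_argument")
  expect_error(chi2_reduced(model, model, length(model)),
               class = "photoacid_invalid_argument")
})

test_that("reduced chi-square averages to one on Poisson counts", {
  model <- 1000 * exp(-(0:299) / 80) + 50
  vals <- vapply(1:100, function(s) {
    set.seed(s)
    chi2_reduced(model, rpois(length(model), model), 0)
  }, numeric(1))
  expect_gt(mean(vals), 0.95)
  expect_lt(mean(vals), 1.05)
})

test_that("fit_spec validates free/fixed sets, bounds and guesses", {
  expect_error(fit_spec(free = "bogus"), class = "photoacid_invalid_argument")
  expect_error(fit_spec(free = "k_PT_per_ns",
                        fixed = list(k_PT_per_ns = 1)),
               class = "photoacid_invalid_argument")
  expect_error(fit_spec(free = "k_PT_per_ns", init = list(k_PT_per_ns = 1e5)),
               class = "photoacid_invalid_argument")
  expect_error(fit_spec(free = character(0)),
               class = "photoacid_invalid_argument")
  fs <- fit_spec(free = c("k_PT_per_ns", "dimensionality_d"))
  expect_s3_class(fs, "fit_spec")
  expect_true(all(fs$init >= fs$lower & fs$init <= fs$upper))
})

test_that("degenerate histograms are rejected up front", {
  irf <- short_irf()
  empty <- structure(list(times = irf$times,
                          counts = integer(length(irf$times)),
                          irf = irf, meta = list()),
                     class = "tcspc_histogram")
  fs <- fit_spec(free = "k_PT_per_ns")
  expect_error(fit_dse_reconvolution(empty, irf, fs),
               class = "photoacid_empty_data")
  expect_error(fit_multiexp_reconvolution(empty, irf),
               class = "photoacid_empty_data")
  dim_hist <- empty
  dim_hist$counts[seq(1, 800, by = 2)] <- 3L  # many channels, all dim
  expect_error(fit_dse_reconvolution(dim_hist, irf, fs),
               class = "photoacid_invalid_argument")
})

test_that("a mono-exponential decay is recovered by the multi-exp fit", {
  irf <- short_irf()
  curve <- emission_curve(irf$times, exp(-irf$times / 5))
  hist <- make_tcspc(curve, irf, peak_counts = 1e4, seed = 3, noise = TRUE)
  fit <- fit_multiexp_reconvolution(hist, irf, n_exp = 3, seed = 3)
  amps <- fit$estimates$amplitudes
  taus <- fit$estimates$tau_ns
  dominant <- which.max(amps)
  expect_rel(taus[dominant], 5, 0.03)
  expect_lt(sum(amps[-dominant]) / sum(amps), 0.02)
  # correctly specified Poisson-noise fit lands near chi2_red = 1
  expect_gt(fit$chi2_red, 0.8)
  expect_lt(fit$chi2_red, 1.2)
  expect_true(fit$converged)
  # lifetimes come out sorted
  expect_true(!is.unsorted(taus))
})

test_that("diffusion-model fit is invariant to amplitude scaling", {
  irf <- short_irf()
  hist <- synth_decay(cfg_2n_buffer, irf, peak_counts = 5e3,
                      noise = FALSE, quantize = FALSE)
  hist10 <- hist
  hist10$counts <- hist$counts * 10
  fs <- fit_spec(free = c("k_PT_per_ns", "k_a_angstrom_per_ns"),
                 fixed = list(dimensionality_d = 3, D_cm2_per_s = 9e-5,
                              R_D_angstrom = 7),
                 n_starts = 2L, seed = 5)
  f1 <- fit_dse_reconvolution(hist, irf, fs)
  f2 <- fit_dse_reconvolution(hist10, irf, fs)
  expect_rel(f2$estimates$k_PT_per_ns, f1$estimates$k_PT_per_ns, 1e-3)
  expect_rel(f2$estimates$amplitude, 10 * f1$estimates$amplitude, 1e-3)
})

test_that("k_PT estimator is unbiased and stable under Poisson noise", {
  irf <- short_irf()
  ests <- vapply(1:12, function(s) {
    hist <- synth_decay(cfg_2n_buffer, irf, peak_counts = 1e4,
                        seed = 100 + s, noise = TRUE)
    fs <- fit_spec(free = c("k_PT_per_ns", "k_a_angstrom_per_ns"),
                   fixed = list(dimensionality_d = 3, D_cm2_per_s = 9e-5,
                                R_D_angstrom = 7),
                   n_starts = 2L, seed = s)
    fit_dse_reconvolution(hist, irf, fs)$estimates$k_PT_per_ns
  }, numeric(1))
  expect_lt(abs(mean(ests) / 0.2 - 1), 0.02)   # relative bias
  expect_lt(sd(ests) / mean(ests), 0.10)       # relative spread
})

test_that("an IRF-limited fast rate is salvaged by the multi-exp fast component", {
  irf <- full_irf()
  # true k_PT of 3.9/ns (tau_PT ~ 0.26 ns) under a 1 ns FWHM pulse
  cfg <- solver_config(a_angstrom = 4, R_D_angstrom = 14, D_cm2_per_s = 9e-5,
                       dimensionality_d = 3, k_PT_per_ns = 3.9,
                       k_a_angstrom_per_ns = 1.5)
  hist <- synth_decay(cfg, irf, peak_counts = 1e4, seed = 11, noise = TRUE)
  fme <- fit_multiexp_reconvolution(hist, irf, n_exp = 3, seed = 11)
  expect_rel(fme$estimates$rate_fast_per_ns, 3.9, 0.20)
  # a diffusion fit anchored on the post-pulse tail underestimates k_PT
  fs <- fit_spec(free = c("k_PT_per_ns", "k_a_angstrom_per_ns"),
                 fixed = list(dimensionality_d = 3, D_cm2_per_s = 9e-5,
                              R_D_angstrom = 14),
                 n_starts = 3L, seed = 5, t_min_ns = 8)
  fdse <- fit_dse_reconvolution(hist, irf, fs)
  expect_lt(fdse$estimates$k_PT_per_ns, 3.9)
})
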