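test_that("lifetime weighting reduces to the populations in the limits", {
  tr <- solve_dse(cfg_2n_buffer, grid_spec(t_max = 10,
                                           output_times = c(1, 5, 10)))
  inf_life <- apply_excited_state_decay(tr, tau_roh = 1e12, tau_ro = 1e12)
  expect_equal(inf_life$roh$intensity, tr$p_bound, tolerance = 1e-9)
  expect_equal(inf_life$ro$intensity, tr$separated_fraction, tolerance = 1e-9)
  # pure radiative decay when nothing dissociates: I_ROH(5) = 1/e at tau 5
  cfg0 <- solver_config(k_PT_per_ns = 0, k_a_angstrom_per_ns = 0)
  tr0 <- solve_dse(cfg0, grid_spec(t_max = 5, output_times = c(1, 5)))
  em <- apply_excited_state_decay(tr0, tau_roh = 5)
  expect_equal(em$roh$intensity[2], exp(-1), tolerance = 1e-9)
  # fully bound initial condition: I_ROH -> 1, I_RO -> 0 at t -> 0
  expect_gt(em$roh$intensity[1], 0.8)
  expect_equal(em$ro$intensity[1], 0)
})

test_that("the discrete Gaussian IRF is normalized, centred and 1 ns wide", {
  irf <- full_irf()
  expect_lt(abs(sum(irf$weights) - 1), 1e-9)
  # centroid at t0 within one channel
  expect_lt(abs(sum(irf$times * irf$weights) - irf$t0), irf$channel_width)
  # discrete FWHM equals the nominal 1 ns within one channel
  half <- max(irf$weights) / 2
  above <- range(irf$times[irf$weights >= half])
  expect_lt(abs(diff(above) - irf$fwhm), 2 * irf$channel_width)
  expect_error(gaussian_irf(fwhm = 0.05), class = "photoacid_under_resolved_irf")
})

test_that("convolution has a delta identity and preserves intensity", {
  irf <- short_irf()
  x <- emission_curve(irf$times, exp(-irf$times / 2))
  delta <- irf
  delta$weights <- c(1, rep(0, length(irf$times) - 1))
  y <- convolve_irf(x, delta)
  expect_equal(y$intensity, x$intensity, tolerance = 1e-10)
  # a decay that dies inside the window keeps its summed intensity
  y2 <- convolve_irf(x, irf)
  expect_rel(sum(y2$intensity), sum(x$intensity), 1e-6)
  bad <- emission_curve(irf$times[-1] + 1, exp(-irf$times[-1] / 2))
  expect_error(convolve_irf(bad, irf), class = "photoacid_invalid_argument")
})

test_that("FFT convolution equals the direct sum and is linear", {
  irf <- gaussian_irf(n_channels = 400L)
  x <- exp(-irf$times / 0.8)
  y <- sin(irf$times / 3)^2
  fft_route <- photoacid:::causal_convolve(x, irf$weights)
  expect_equal(fft_route, direct_convolve(x, irf$weights), tolerance = 1e-10)
  lin <- photoacid:::causal_convolve(2 * x + 0.5 * y, irf$weights)
  ref <- 2 * fft_route + 0.5 * photoacid:::causal_convolve(y, irf$weights)
  expect_equal(lin, ref, tolerance = 1e-10)
})

test_that("a fast decay convolved with the IRF peaks near the IRF peak", {
  irf <- short_irf()
  fast <- emission_curve(irf$times, exp(-irf$times / 0.1))
  y <- convolve_irf(fast, irf)
  t_peak <- y$times[which.max(y$intensity)]
  t_irf <- irf$times[which.max(irf$weights)]
  expect_lt(abs(t_peak - t_irf), 0.2)
})

test_that("spectral synthesis/unmixing round trips at the measured ratios", {
  for (pa in registry) {
    for (r in c(pa$ratio_free, pa$ratio_bound)) {
      sp <- synth_spectrum(r, pa$bands)
      expect_rel(measure_ratio(sp, pa$bands), r, 0.01)
    }
  }
})

test_that("ratio estimation is scale-invariant and robust to mild noise", {
  b <- registry[["2N6,8S"]]$bands
  sp <- synth_spectrum(48.5, b)
  scaled <- steady_spectrum(sp$wavelengths, sp$intensity * 123.4)
  expect_equal(measure_ratio(scaled, b), measure_ratio(sp, b),
               tolerance = 1e-12)
  for (r in c(0.01, 0.5, 6.4, 100)) {
    # 1% relative noise on every point; judge the error distribution
    # over replicate draws (a single draw has a stochastic tail)
    errs <- vapply(1:10, function(s) {
      spr <- synth_spectrum(r, b)
      noisy <- with(spr, steady_spectrum(wavelengths, pmax(
        intensity * (1 + seeded_rnorm(length(intensity), 0.01, s)), 0)))
      abs(measure_ratio(noisy, b) / r - 1)
    }, numeric(1))
    expect_lt(median(errs), 0.05)
    expect_lt(max(errs), 0.10)
  }
})

test_that("ratio zero, bathochromic shift and degenerate bands behave", {
  b <- band_model(roh_center = 355)
  sp0 <- synth_spectrum(0, b)
  expect_equal(measure_ratio(sp0, b), 0)
  # +5 nm shift moves the RO-* apex by 5 nm, ROH apex unchanged
  b5 <- band_model(roh_center = 355, bathochromic_shift_nm = 5)
  sp <- synth_spectrum(20, b)
  sp5 <- synth_spectrum(20, b5)
  expect_equal(b5$ro_center, b$ro_center + 5)
  expect_equal(sp5$wavelengths[which.max(sp5$intensity)],
               sp$wavelengths[which.max(sp$intensity)] + 5)
  degenerate <- b
  degenerate$ro_center <- degenerate$roh_center
  expect_error(measure_ratio(sp, degenerate),
               class = "photoacid_unidentifiable_model")
})

test_that("unmixing agrees with an exhaustive amplitude grid search", {
  b <- band_model(roh_center = 355)
  wl <- seq(300, 520, length.out = 50)
  sp <- synth_spectrum(3.7, b, wavelengths = wl)
  B <- photoacid:::band_matrix(b, wl)
  rss <- function(b1, b2) sum((sp$intensity - B %*% c(b1, b2))^2)
  # coarse-to-fine search over the two amplitudes
  ctr <- c(1, 3.7); span <- c(2, 5)
  for (lvl in 1:6) {
    g1 <- seq(max(0, ctr[1] - span[1]), ctr[1] + span[1], length.out = 41)
    g2 <- seq(max(0, ctr[2] - span[2]), ctr[2] + span[2], length.out = 41)
    val <- outer(g1, g2, Vectorize(rss))
    ix <- which(val == min(val), arr.ind = TRUE)[1, ]
    ctr <- c(g1[ix[1]], g2[ix[2]]); span <- span / 10
  }
  expect_rel(measure_ratio(sp, b), ctr[2] / ctr[1], 1e-3)
})
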