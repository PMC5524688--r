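test_that("without recombination the bound state decays mono-exponentially", {
  cfg <- solver_config(k_PT_per_ns = 0.2, k_a_angstrom_per_ns = 0,
                       R_D_angstrom = 7)
  tr <- solve_dse(cfg, grid_spec(t_max = 10, output_times = c(1, 2, 5, 10)))
  expect_lt(max(abs(tr$p_bound - exp(-0.2 * tr$times))), 1e-4)
  # P(5 ns) = 1/e
  expect_equal(tr$p_bound[3], exp(-1), tolerance = 1e-4)
})

test_that("without dissociation the bound state never decays", {
  cfg <- solver_config(k_PT_per_ns = 0, k_a_angstrom_per_ns = 0.5,
                       R_D_angstrom = 7)
  tr <- solve_dse(cfg, grid_spec(t_max = 10, output_times = c(1, 5, 10)))
  expect_identical(tr$p_bound, rep(1, 3))
  expect_identical(tr$separated_fraction, rep(0, 3))
})

test_that("probability is conserved and p_bound stays in [0, 1]", {
  for (cond in c("buffer", "fibril")) {
    cfg <- registry[["2N6,8S"]][[cond]]
    tr <- solve_dse(cfg, grid_spec(t_max = 50))
    expect_lte(tr$mass_balance_error, 1e-4)
    expect_true(all(tr$p_bound >= 0 & tr$p_bound <= 1))
    expect_equal(tr$p_bound + tr$separated_fraction, rep(1, length(tr$times)))
  }
})

test_that("p_bound is monotone in the rates across a parameter lattice", {
  grid <- grid_spec(t_max = 20, output_times = c(1, 5, 20))
  kpts <- c(0.2, 0.8, 2)
  kas <- c(0.1, 0.7, 3)
  pb <- array(dim = c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    cfg <- solver_config(k_PT_per_ns = kpts[i], k_a_angstrom_per_ns = kas[j],
                         R_D_angstrom = 10)
    pb[i, j, ] <- solve_dse(cfg, grid)$p_bound
  }
  for (j in 1:3) for (k in 1:3)   # non-increasing in k_PT
    expect_true(all(diff(pb[, j, k]) <= 1e-12))
  for (i in 1:3) for (k in 1:3)   # non-decreasing in k_a
    expect_true(all(diff(pb[i, , k]) >= -1e-12))
})

test_that("absorbing limit matches the closed-form Smoluchowski survival", {
  cfg <- solver_config(a_angstrom = 4, R_D_angstrom = 0, D_cm2_per_s = 9e-5,
                       dimensionality_d = 3, k_PT_per_ns = 0,
                       k_a_angstrom_per_ns = 1e5)
  ots <- exp(seq(log(0.1), log(50), length.out = 12))
  tr <- solve_dse(cfg, grid_spec(t_max = 50, output_times = ots),
                  initial = "delta", r0 = 8)
  ref <- smoluchowski_survival(4, cfg$D_angstrom2_per_ns, 8, ots)
  expect_lt(max(abs(tr$separated_fraction / ref - 1)), 0.01)
})

test_that("the long-time tail follows the t^(-d/2) law", {
  for (dd in c(1.2, 2, 3)) {
    cfg <- solver_config(a_angstrom = 4, R_D_angstrom = 7, D_cm2_per_s = 9e-5,
                         dimensionality_d = dd, k_PT_per_ns = 2,
                         k_a_angstrom_per_ns = 0.5)
    tr <- solve_dse(cfg, grid_spec(t_max = 400))
    expect_rel(tail_slope(tr, c(40, 400)), -dd / 2, 0.05)
  }
})

test_that("the solver tail tracks the asymptotic ROH* form up to a constant", {
  tr <- solve_dse(cfg_2n_buffer, grid_spec(t_max = 200))
  sel <- tr$times >= 100
  ratio <- tr$p_bound[sel] / asymptotic_roh(tr$times[sel], cfg_2n_buffer)
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.1)
})

test_that("asymptotic_roh has the stated parameter dependences", {
  cfg <- cfg_2n_buffer
  cfg2 <- solver_config(a_angstrom = 4, R_D_angstrom = 7, D_cm2_per_s = 9e-5,
                        dimensionality_d = 3, k_PT_per_ns = 0.4,
                        k_a_angstrom_per_ns = 0.2)
  # doubling k_PT halves the value; pure t^(-d/2) power law
  expect_equal(asymptotic_roh(10, cfg2), asymptotic_roh(10, cfg) / 2)
  expect_equal(asymptotic_roh(40, cfg) / asymptotic_roh(10, cfg), 4^(-1.5))
  expect_true(all(diff(asymptotic_roh(c(1, 2, 5, 10), cfg)) < 0))
  cfg0 <- solver_config(k_PT_per_ns = 0, k_a_angstrom_per_ns = 1)
  expect_error(asymptotic_roh(1, cfg0), class = "photoacid_invalid_argument")
})

test_that("grid refinement changes the solution by less than 0.5%", {
  ots <- exp(seq(log(0.1), log(100), length.out = 8))
  g <- grid_spec(t_max = 100, output_times = ots)
  cfg <- registry[["2N8S"]]$fibril
  t1 <- solve_dse(cfg, g)
  t2 <- solve_dse(cfg, refine_grid(g))
  expect_lt(max(abs(t1$p_bound / t2$p_bound - 1)), 0.005)
})

test_that("characteristic times invert the rates", {
  cfg <- solver_config(k_PT_per_ns = 0.2, k_a_angstrom_per_ns = 0.8)
  expect_equal(tau_pt(cfg), 5)
  expect_equal(tau_a(cfg), 1.25)
  idle <- solver_config(k_PT_per_ns = 0, k_a_angstrom_per_ns = 0)
  expect_identical(tau_pt(idle), Inf)
  expect_identical(tau_a(idle), Inf)
})

test_that("invalid configurations and domains are rejected", {
  expect_error(solver_config(a_angstrom = -1),
               class = "photoacid_invalid_argument")
  expect_error(solver_config(dimensionality_d = 0.4),
               class = "photoacid_invalid_argument")
  expect_error(solver_config(k_PT_per_ns = -1),
               class = "photoacid_invalid_argument")
  expect_error(grid_spec(t_max = 10, output_times = c(5, 20)),
               class = "photoacid_invalid_argument")
  cfg <- solver_config(k_PT_per_ns = 1, k_a_angstrom_per_ns = 1,
                       R_D_angstrom = 7)
  expect_error(solve_dse(cfg, grid_spec(t_max = 5), initial = "delta", r0 = 2),
               class = "photoacid_invalid_argument")
  # outer boundary far too close: density reaches it and the run is rejected
  expect_error(
    solve_dse(cfg, grid_spec(t_max = 50, r_max = 60, n_r = 100)),
    class = "photoacid_domain_too_small")
})
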