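# photoacid

Kinetic analysis of excited-state proton transfer (ESPT) from
2-naphthol-family photoacids, free in buffer and bound to insulin
amyloid fibrils — for spectroscopists who use photoacids as probes of
proton mobility and hydration at biomolecular surfaces.

Upon excitation a photoacid ROH\* releases its proton (rate *k*<sub>PT</sub>);
the geminate RO⁻\*…H⁺ pair either recombines at the contact sphere
(radius *a*, intrinsic velocity *k*<sub>a</sub>) or the proton escapes by
diffusion (*D*) in the anion's Coulomb field (Debye radius
*R*<sub>D</sub> = |*Z*₁*Z*₂|e²/4πε₀ε<sub>r</sub>k<sub>B</sub>T), in an
effective dimensionality *d* that drops from 3 in bulk water toward 2–1
on a fibril surface.  The package provides:

* a finite-volume Crank–Nicolson solver for the spherically-symmetric
  Debye–Smoluchowski equation with back-reaction boundary condition and
  fractional *d* (`solve_dse()`), validated against a closed-form
  Smoluchowski oracle and a Brownian-dynamics simulation
  (`smoluchowski_survival()`, `brownian_geminate()`);
* TCSPC reconvolution fitting of ROH\* decays — the full diffusion model
  (`fit_dse_reconvolution()`) and a multi-exponential backup for
  IRF-limited fast rates (`fit_multiexp_reconvolution()`);
* Debye radii (`debye_radius()`), steady-state two-band RO⁻\*/ROH\*
  spectra (`synth_spectrum()`, `measure_ratio()`), and logistic
  amyloidogenesis traces (`amyloid_trace()`, `fit_amyloid_kinetics()`);
* a synthetic-data module holding the published parameter registry of
  the four photoacids 2N, 2N6S, 2N8S and 2N6,8S
  (`photoacid_registry()`, `make_tcspc()`), and a pipeline that
  regenerates the full kinetic table (`run_table1_report()`).

See `vignettes/photoacid-kinetics.Rmd` for the model, conventions and
numerical choices.

## Worked example

Simulate 2-naphthol-6-sulfonate (2N6S) in pH 7 buffer, synthesise its
TCSPC decay under a 1 ns FWHM pulse with Poisson counting noise at 10⁴
peak counts, and refit it with the in-buffer scheme (diffusion constant,
dimensionality and Debye radius fixed at their bulk-water values):

```r
library(photoacid)

reg <- photoacid_registry()
cfg <- reg[["2N6S"]]$buffer
cfg
#> <solver_config> a = 4 A, R_D = 14 A, D = 9e-05 cm2/s, d = 3, k_PT = 1 /ns, k_a = 0.8 A/ns

irf  <- gaussian_irf()                       # 1 ns FWHM, 0.055 ns channels
hist <- synth_decay(cfg, irf, peak_counts = 1e4, seed = 1, noise = TRUE)

spec <- fit_spec(free  = c("k_PT_per_ns", "k_a_angstrom_per_ns"),
                 fixed = list(dimensionality_d = 3, D_cm2_per_s = 9e-5,
                              R_D_angstrom = round(debye_radius(2, 1))))
fit <- fit_dse_reconvolution(hist, irf, spec)
fit
#> <fit_result> converged (chi2_red = 0.868)
#>   k_PT_per_ns            0.984873 +/- 0.0044
#>   k_a_angstrom_per_ns    0.430568 +/- 0.075
#>   amplitude              19772.1
#>   baseline               0.732644
```

The proton-transfer rate comes back at 0.985 ns⁻¹ (1.5% from the
generating 1.0 ns⁻¹ — τ_PT ≈ 1 ns, the fast initial decay), and
`chi2_red ≈ 1` says the model accounts for the data at counting-noise
level.  The recombination velocity *k*<sub>a</sub> lands at 0.43 Å/ns
against a generating 0.8: its information lives in the dim geminate
tail, so at 10⁴ peak counts it is only weakly determined from a single
decay (noiseless round trips recover it to machine precision — see the
vignette).  Debye radii for the four photoacids (anion charges
1, 2, 2, 3):

```r
round(sapply(c(1, 2, 2, 3), debye_radius, z2 = 1))
#> [1]  7 14 14 21
```

And the steady-state band-ratio machinery round-trips the measured
RO⁻\*/ROH\* ratios, e.g. for fibril-bound 2N6,8S:

```r
b <- reg[["2N6,8S"]]$bands
measure_ratio(synth_spectrum(6.4, b), b)
#> [1] 6.4
```

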