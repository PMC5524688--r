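#' Physical configuration of the geminate recombination problem
#'
#' Collects the parameters of the photoprotolytic cycle: contact radius
#' `a`, Debye radius `R_D` (0 means no interaction potential), proton
#' diffusion coefficient `D`, effective diffusion dimensionality `d`,
#' proton-transfer (dissociation) rate `k_PT` and intrinsic contact
#' recombination velocity `k_a`.  The diffusion coefficient is accepted in
#' cm^2/s and converted exactly once here to the internal A^2/ns unit
#' system (1 cm^2/s = 1e7 A^2/ns).
#'
#' The recombination convention: the total recombination flux is
#' `k_a * A_d(a) * p(a, t)` with the generalized contact surface
#' `A_d(a) = (2 pi^(d/2) / Gamma(d/2)) a^(d-1)`, and the pair density `p`
#' normalized per generalized volume, so probability is conserved for any
#' real dimensionality.
#'
#' @param a_angstrom contact (reaction sphere) radius in angstrom.
#' @param R_D_angstrom Debye radius in angstrom (>= 0; attractive
#'   potential `V(r) = -R_D/r` in kB*T units).
#' @param D_cm2_per_s proton diffusion coefficient in cm^2/s.
#' @param dimensionality_d effective dimensionality, real in (0.5, 3].
#' @param k_PT_per_ns excited-state proton transfer rate in 1/ns (>= 0).
#' @param k_a_angstrom_per_ns intrinsic recombination velocity in A/ns
#'   (>= 0).
#' @param Z1,Z2 optional integer charges of anion and proton, carried as
#'   metadata (the potential itself is set by `R_D_angstrom`).
#' @return An object of class `solver_config`.
#' @examples
#' # 2-naphthol free in pH 7 buffer
#' solver_config(a_angstrom = 4, R_D_angstrom = 7, D_cm2_per_s = 9e-5,
#'               dimensionality_d = 3, k_PT_per_ns = 0.2,
#'               k_a_angstrom_per_ns = 0.2)
#' @export
solver_config <- function(a_angstrom = 4, R_D_angstrom = 0,
                          D_cm2_per_s = 9e-5, dimensionality_d = 3,
                          k_PT_per_ns = 0, k_a_angstrom_per_ns = 0,
                          Z1 = NA_integer_, Z2 = 1L) {
  for (nm in c("a_angstrom", "R_D_angstrom", "D_cm2_per_s",
               "dimensionality_d", "k_PT_per_ns", "k_a_angstrom_per_ns"))
    stopifnot_finite(get(nm), nm)
  if (a_angstrom <= 0) pa_stop("invalid_argument", "a_angstrom must be > 0")
  if (R_D_angstrom < 0) pa_stop("invalid_argument", "R_D_angstrom must be >= 0")
  if (D_cm2_per_s <= 0) pa_stop("invalid_argument", "D_cm2_per_s must be > 0")
  if (dimensionality_d <= 0.5 || dimensionality_d > 3)
    pa_stop("invalid_argument", "dimensionality_d must lie in (0.5, 3]")
  if (k_PT_per_ns < 0 || k_a_angstrom_per_ns < 0)
    pa_stop("invalid_argument", "rates must be >= 0")
  structure(
    list(a_angstrom = a_angstrom,
         R_D_angstrom = R_D_angstrom,
         D_cm2_per_s = D_cm2_per_s,
         D_angstrom2_per_ns = D_cm2_per_s * 1e7,  # single conversion point
         dimensionality_d = dimensionality_d,
         k_PT_per_ns = k_PT_per_ns,
         k_a_angstrom_per_ns = k_a_angstrom_per_ns,
         Z1 = Z1, Z2 = Z2),
    class = "solver_config")
}

#' @export
print.solver_config <- function(x, ...) {
  cat(sprintf(paste0("<solver_config> a = %g A, R_D = %g A, D = %g cm2/s,",
                     " d = %g, k_PT = %g /ns, k_a = %g A/ns\n"),
              x$a_angstrom, x$R_D_angstrom, x$D_cm2_per_s,
              x$dimensionality_d, x$k_PT_per_ns, x$k_a_angstrom_per_ns))
  invisible(x)
}

#' Characteristic times of the photoprotolytic cycle
#'
#' `tau_pt()` is the proton-transfer time `1/k_PT` (the fast initial decay
#' of the ROH* band); `tau_a()` is the recombination time `1/k_a`.
#' Both are `Inf` when the corresponding rate is zero.
#'
#' @param config a [solver_config()].
#' @return time in ns (`tau_pt`) or ns*A-1-scaled inverse velocity
#'   (`tau_a`, in ns per (A/ns) units of `k_a`).
#' @export
tau_pt <- function(config) {
  if (config$k_PT_per_ns == 0) Inf else 1 / config$k_PT_per_ns
}

#' @rdname tau_pt
#' @export
tau_a <- function(config) {
  if (config$k_a_angstrom_per_ns == 0) Inf else 1 / config$k_a_angstrom_per_ns
}

#' Numerical grid controls for the diffusion solver
#'
#' The radial coordinate is discretised on a geometric grid clustered at
#' the contact radius (first spacing `h0`); time stepping ramps
#' geometrically from `dt0` up to `dt_max`.  Defaults resolve the stiff
#' early-time contact flux while keeping a full 200 ns window cheap.
#'
#' @param t_max final time in ns.
#' @param output_times increasing times (ns) at which the solution is
#'   reported; default 200 log-spaced points in `[dt0, t_max]`.
#' @param n_r number of radial nodes (>= 100).
#' @param r_max outer (reflecting) boundary in angstrom; `NULL` selects
#'   `max(20 R_D, 10 sqrt(2 D t_max), 200)` at solve time so that the
#'   domain emulates an infinite medium.
#' @param h0 first radial spacing at the contact radius, angstrom.
#' @param dt0 initial time step, ns.
#' @param dt_max time-step ceiling, ns; `NULL` selects `t_max/400`.
#' @param growth geometric time-step growth factor.
#' @param transient_frac while the dissociation transient is alive
#'   (`t < 14/k_PT`), the step is additionally capped at
#'   `transient_frac / k_PT` so a fast exponential stays resolved.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(t_max, output_times = NULL, n_r = 400L, r_max = NULL,
                      h0 = 0.01, dt0 = 1e-4, dt_max = NULL, growth = 1.05,
                      transient_frac = 0.08) {
  stopifnot_finite(t_max, "t_max")
  if (t_max <= 0) pa_stop("invalid_argument", "t_max must be > 0")
  if (n_r < 100) pa_stop("invalid_argument", "n_r must be >= 100")
  if (dt0 <= 0) pa_stop("invalid_argument", "dt0 must be > 0")
  if (!is.null(dt_max) && dt_max < dt0)
    pa_stop("invalid_argument", "dt_max must be >= dt0")
  if (growth < 1) pa_stop("invalid_argument", "growth must be >= 1")
  if (is.null(output_times))
    output_times <- exp(seq(log(dt0 * 10), log(t_max), length.out = 200))
  stopifnot_finite(output_times, "output_times")
  if (is.unsorted(output_times, strictly = TRUE))
    pa_stop("invalid_argument", "output_times must be strictly increasing")
  if (max(output_times) > t_max * (1 + 1e-12))
    pa_stop("invalid_argument", "all output_times must be <= t_max")
  structure(
    list(t_max = t_max, output_times = output_times, n_r = as.integer(n_r),
         r_max = r_max, h0 = h0, dt0 = dt0,
         dt_max = dt_max %||% (t_max / 400), growth = growth,
         transient_frac = transient_frac),
    class = "grid_spec")
}

#' Refine a grid specification
#'
#' Returns the same grid with the radial node count doubled and the time
#' discretisation halved (`dt0`, `dt_max` halved, growth square-rooted).
#' Used by the grid-convergence checks.
#'
#' @param grid a [grid_spec()].
#' @return a refined `grid_spec`.
#' @export
refine_grid <- function(grid) {
  grid_spec(t_max = grid$t_max, output_times = grid$output_times,
            n_r = grid$n_r * 2L, r_max = grid$r_max, h0 = grid$h0 / 2,
            dt0 = grid$dt0 / 2, dt_max = grid$dt_max / 2,
            growth = sqrt(grid$growth),
            transient_frac = grid$transient_frac / 2)
}

# geometric node ladder from a to r_max, first spacing ~h0
radial_nodes <- function(a, r_max, n_r, h0) {
  L <- r_max - a
  if (h0 * (n_r - 1) >= L)          # uniform grid is already fine enough
    return(seq(a, r_max, length.out = n_r))
  f <- function(g) h0 * (g^(n_r - 1) - 1) / (g - 1) - L
  g <- uniroot(f, c(1 + 1e-10, 3), tol = 1e-14)$root
  a + c(0, cumsum(h0 * g^(0:(n_r - 2))))
}

#' Solve the Debye-Smoluchowski geminate recombination problem
#'
#' Evolves the pair density `p(r, t)` under
#' `dp/dt = r^(1-d) d_r [ r^(d-1) D (d_r p + p d_r V) ]` with the
#' attractive Coulomb potential `V(r) = -R_D/r` (kB*T units), coupled to
#' the bound ROH* population through the back-reaction boundary condition
#' at the contact radius: `dP/dt = -k_PT P + k_a A_d(a) p(a, t)`, with
#' the matching contact flux and a reflecting outer boundary.  Total
#' probability (bound + integrated pair density) is conserved.
#'
#' @param config a [solver_config()].
#' @param grid a [grid_spec()].
#' @param initial `"bound"` (all population in ROH*, the photoexcitation
#'   initial condition) or `"delta"` (an unbound pair at separation `r0`,
#'   used by the validation oracles).
#' @param r0 initial separation in angstrom for `initial = "delta"`
#'   (must be >= the contact radius).
#' @param conservation_tol maximum tolerated drift of total probability;
#'   a larger drift raises a numerical-failure condition.
#' @param domain_tol maximum tolerated fraction of the pair density in
#'   the 5 outermost cells at the final time; more raises a
#'   domain-too-small condition.
#' @return An object of class `kinetic_trace` with elements `times`,
#'   `p_bound` (ROH* survival probability), `p_contact` (pair density at
#'   contact, per generalized volume), `separated_fraction`
#'   (`1 - p_bound`), and `mass_balance_error`.
#' @examples
#' cfg <- solver_config(k_PT_per_ns = 0.2, R_D_angstrom = 7,
#'                      k_a_angstrom_per_ns = 0.2)
#' tr <- solve_dse(cfg, grid_spec(t_max = 10, output_times = c(1, 5, 10)))
#' tr$p_bound
#' @export
solve_dse <- function(config, grid, initial = c("bound", "delta"), r0 = NULL,
                      conservation_tol = 1e-4, domain_tol = 1e-6) {
  if (!inherits(config, "solver_config"))
    pa_stop("invalid_argument", "config must be a solver_config")
  if (!inherits(grid, "grid_spec"))
    pa_stop("invalid_argument", "grid must be a grid_spec")
  initial <- match.arg(initial)

  a <- config$a_angstrom
  D <- config$D_angstrom2_per_ns
  r_max <- grid$r_max %||%
    max(20 * config$R_D_angstrom, 10 * sqrt(2 * D * grid$t_max), 200)
  if (r_max <= a) pa_stop("invalid_argument", "r_max must exceed a")
  r <- radial_nodes(a, r_max, grid$n_r, grid$h0)

  p0 <- numeric(length(r))
  P0 <- 1
  if (initial == "delta") {
    if (is.null(r0) || !is.finite(r0) || r0 < a)
      pa_stop("invalid_argument", "delta initial condition requires r0 >= a")
    if (r0 >= r_max)
      pa_stop("invalid_argument", "r0 must be inside the domain")
    P0 <- 0
    # split the unit delta over the two bracketing cells so the mean
    # initial separation equals r0 exactly (second-order placement)
    j <- findInterval(r0, r)
    vols <- cell_volumes(r, config$dimensionality_d)
    if (j >= length(r)) {
      p0[j] <- 1 / vols[j]
    } else {
      lam <- (r0 - r[j]) / (r[j + 1] - r[j])
      p0[j] <- (1 - lam) / vols[j]
      p0[j + 1] <- lam / vols[j + 1]
    }
  }

  sol <- dse_solve_cpp(r, config$R_D_angstrom, D, config$dimensionality_d,
                       config$k_PT_per_ns, config$k_a_angstrom_per_ns,
                       P0, p0, grid$t_max, grid$dt0, grid$dt_max,
                       grid$growth, 8L,
                       grid$transient_frac %||% 0.08)

  if (sol$mass_balance_error > conservation_tol)
    pa_stop("numerical_failure",
            "probability drift %.3g exceeds tolerance %.3g",
            sol$mass_balance_error, conservation_tol)
  if (sol$tail_fraction > domain_tol)
    pa_stop("domain_too_small",
            "density fraction %.3g near r_max = %g A exceeds %.3g; enlarge r_max",
            sol$tail_fraction, r_max, domain_tol)

  tt <- grid$output_times
  pb <- interp_decay(sol$times, sol$P, tt)
  pc <- interp_decay(sol$times, sol$p_contact, tt)
  pb <- pmin(pmax(pb, 0), 1)

  structure(
    list(times = tt, p_bound = pb, p_contact = pc,
         separated_fraction = 1 - pb,
         mass_balance_error = sol$mass_balance_error,
         config = config, grid = grid, initial = initial,
         n_steps = sol$n_steps),
    class = "kinetic_trace")
}

# generalized cell volumes for the finite-volume grid (mirrors the C++ side)
cell_volumes <- function(r, d) {
  n <- length(r)
  Sd <- 2 * pi^(d / 2) / gamma(d / 2)
  b <- c(r[1], (r[-n] + r[-1]) / 2, r[n])
  Sd * (b[-1]^d - b[-(n + 1)]^d) / d
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf(paste0("<kinetic_trace> %d output times in [%.3g, %.3g] ns; ",
                     "P_bound: %.4g -> %.4g; |mass drift| = %.2g\n"),
              length(x$times), min(x$times), max(x$times),
              x$p_bound[1], x$p_bound[length(x$p_bound)],
              x$mass_balance_error))
  invisible(x)
}

#' Long-time asymptotic ROH* intensity
#'
#' Closed-form long-time limit of the ROH* survival under the geminate
#' recombination model:
#' `pi a^2 k_a exp(-R_D/a) / (2 k_PT (pi D t)^(d/2))`,
#' a pure `t^(-d/2)` power law.  Used to check the solver's tail.
#'
#' @param t time(s) in ns, > 0.
#' @param config a [solver_config()] with `k_PT > 0`.
#' @return relative intensity (same arbitrary scale as the ROH* survival).
#' @export
asymptotic_roh <- function(t, config) {
  if (!inherits(config, "solver_config"))
    pa_stop("invalid_argument", "config must be a solver_config")
  if (config$k_PT_per_ns == 0)
    pa_stop("invalid_argument", "asymptotic form undefined for k_PT = 0")
  stopifnot_finite(t, "t")
  if (any(t <= 0)) pa_stop("invalid_argument", "t must be > 0")
  a <- config$a_angstrom
  D <- config$D_angstrom2_per_ns
  pi * a^2 * config$k_a_angstrom_per_ns * exp(-config$R_D_angstrom / a) /
    (2 * config$k_PT_per_ns * (pi * D * t)^(config$dimensionality_d / 2))
}

#' Log-log tail slope of a kinetic trace
#'
#' Least-squares slope of `log(p_bound)` against `log(t)` over a time
#' window; at long times the geminate model predicts a slope of `-d/2`.
#'
#' @param trace a `kinetic_trace`.
#' @param t_window numeric length-2 window in ns.
#' @return the fitted slope (dimensionless).
#' @export
tail_slope <- function(trace, t_window) {
  sel <- trace$times >= t_window[1] & trace$times <= t_window[2] &
    trace$p_bound > 0
  if (sum(sel) < 3)
    pa_stop("invalid_argument", "need >= 3 positive points in the window")
  x <- log(trace$times[sel])
  y <- log(trace$p_bound[sel])
  unname(coef(stats::lm.fit(cbind(1, x), y))[2])
}
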