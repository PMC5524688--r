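#' Closed-form Smoluchowski survival probability
#'
#' Survival probability of a freely diffusing pair (3D, no potential)
#' started at separation `r0` with a perfectly absorbing contact sphere
#' of radius `a`:
#' `S(t) = 1 - (a/r0) erfc[(r0 - a) / sqrt(4 D t)]`.
#' Serves as an independent oracle for the solver in the absorbing limit
#' (large `k_a`, `k_PT = 0`, `R_D = 0`, `d = 3`).
#'
#' @param a contact radius, angstrom.
#' @param D diffusion coefficient, A^2/ns.
#' @param r0 initial separation, angstrom (>= a).
#' @param t time(s), ns (>= 0).
#' @return survival probability in `[1 - a/r0, 1]`.
#' @export
smoluchowski_survival <- function(a, D, r0, t) {
  stopifnot_finite(c(a, D, r0), "a, D, r0")
  stopifnot_finite(t, "t")
  if (r0 < a) pa_stop("invalid_argument", "r0 must be >= a")
  if (any(t < 0)) pa_stop("invalid_argument", "t must be >= 0")
  s <- ifelse(t == 0, 1, 1 - (a / r0) * erfc((r0 - a) / sqrt(4 * D * t)))
  as.numeric(s)
}

#' Brownian-dynamics oracle for the geminate problem
#'
#' Independent stochastic reference for [solve_dse()]: Euler-Maruyama
#' walkers follow the radial Ito dynamics
#' `dr = [ (d-1) D / r - D R_D / r^2 ] dt + sqrt(2 D) dW`, bound walkers
#' dissociate at rate `k_PT` (exact exponential sampling) and free
#' walkers reaching the contact sphere are reflected and rebind with the
#' radiation-boundary probability `k_a sqrt(pi dt / D)` per crossing.
#' Results depend only on the arguments including `seed`.
#'
#' @param config a [solver_config()].
#' @param n_particles number of walkers (>= 1e4 for useful errors).
#' @param output_times increasing times (ns).
#' @param dt integration step, ns; the per-crossing reaction probability
#'   `k_a sqrt(pi dt / D)` must stay below 1%.
#' @param seed integer seed for the private RNG stream.
#' @param initial `"bound"` or `"delta"` (at `r0`).
#' @param r0 initial separation for `initial = "delta"`.
#' @return data.frame with columns `time`, `p_bound` and the binomial
#'   standard error `se`.
#' @export
brownian_geminate <- function(config, n_particles, output_times,
                              dt = 5e-4, seed = 1L,
                              initial = c("bound", "delta"), r0 = NULL) {
  if (!inherits(config, "solver_config"))
    pa_stop("invalid_argument", "config must be a solver_config")
  initial <- match.arg(initial)
  if (n_particles < 1e4)
    pa_stop("invalid_argument", "n_particles must be >= 1e4")
  if (is.unsorted(output_times, strictly = TRUE))
    pa_stop("invalid_argument", "output_times must be strictly increasing")
  D <- config$D_angstrom2_per_ns
  p_react <- config$k_a_angstrom_per_ns * sqrt(pi * dt / D)
  if (p_react > 0.01)
    pa_stop("invalid_configuration",
            "per-step reaction probability %.3g > 1%%; reduce dt", p_react)
  if (initial == "delta") {
    if (is.null(r0) || r0 < config$a_angstrom)
      pa_stop("invalid_argument", "delta initial condition requires r0 >= a")
  } else r0 <- config$a_angstrom
  m <- bd_geminate_cpp(config$a_angstrom, config$R_D_angstrom, D,
                       config$dimensionality_d, config$k_PT_per_ns,
                       config$k_a_angstrom_per_ns, as.integer(n_particles),
                       as.numeric(output_times), dt, r0,
                       initial == "bound", as.integer(seed))
  as.data.frame(m)
}
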