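# Synthetic-data module: the photoacid registry, TCSPC histogram
# generation with Poisson counting noise, and amyloidogenesis traces.

#' Registry of the four 2-naphthol photoacids
#'
#' Returns the parameter sets of 2-naphthol (2N) and its 6-, 8- and
#' 6,8-sulfonated derivatives, free in pH 7 buffer and bound to insulin
#' amyloid fibrils: anion charge, ground- and excited-state pKa, the
#' kinetic parameters of the geminate recombination model for both
#' conditions, the steady-state RO-*/ROH* band ratios and the band
#' model.  Values are read from the checked-in constants table
#' (`inst/extdata/table1_photoacids.csv`), so any edit there is caught
#' by the test suite.
#'
#' @return named list of 4 `photoacid_spec` objects
#'   (`"2N"`, `"2N6S"`, `"2N8S"`, `"2N6,8S"`), each with elements
#'   `name`, `Z1`, `pKa`, `pKa_star`, `buffer` and `fibril`
#'   ([solver_config()]s), `bands` ([band_model()]), `ratio_free`,
#'   `ratio_bound`, `collection_nm` and `rate_fast_reconv`.
#' @examples
#' reg <- photoacid_registry()
#' reg[["2N6S"]]$buffer$k_PT_per_ns
#' @export
photoacid_registry <- function() {
  path <- system.file("extdata", "table1_photoacids.csv",
                      package = "photoacid", mustWork = TRUE)
  tab <- read.table(path, sep = ",", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  names_u <- unique(tab$name)
  specs <- lapply(names_u, function(nm) {
    rows <- tab[tab$name == nm, ]
    cfg <- function(cond) {
      r <- rows[rows$condition == cond, ]
      solver_config(a_angstrom = r$a_angstrom,
                    R_D_angstrom = r$R_D_angstrom,
                    D_cm2_per_s = r$D_cm2_per_s,
                    dimensionality_d = r$dimensionality_d,
                    k_PT_per_ns = r$k_PT_per_ns,
                    k_a_angstrom_per_ns = r$k_a_angstrom_per_ns,
                    Z1 = as.integer(r$Z1), Z2 = 1L)
    }
    b <- rows[rows$condition == "buffer", ]
    structure(
      list(name = nm, Z1 = as.integer(b$Z1), pKa = b$pKa,
           pKa_star = b$pKa_star,
           buffer = cfg("buffer"), fibril = cfg("fibril"),
           bands = band_model(roh_center = b$roh_center_nm,
                              ro_center = b$ro_center_nm),
           ratio_free = b$ratio,
           ratio_bound = rows[rows$condition == "fibril", ]$ratio,
           collection_nm = b$collection_nm,
           rate_fast_reconv = b$rate_fast_reconv),
      class = "photoacid_spec")
  })
  setNames(specs, names_u)
}

#' @export
print.photoacid_spec <- function(x, ...) {
  cat(sprintf("<photoacid_spec> %s: Z1 = %d, pKa* = %g, k_PT(buffer) = %g /ns\n",
              x$name, x$Z1, x$pKa_star, x$buffer$k_PT_per_ns))
  invisible(x)
}

#' Synthesise a TCSPC photon histogram
#'
#' Convolves an emission curve with the IRF, scales it so the expected
#' peak (including a flat background) equals `peak_counts`, and draws
#' Poisson counts (or rounds deterministically with `noise = FALSE`).
#' A pure function of its arguments including `seed`.
#'
#' @param curve an [emission_curve()] on the IRF's channel grid.
#' @param irf a [gaussian_irf()].
#' @param peak_counts target expected counts in the peak channel (>= 1).
#' @param background expected background counts per channel.
#' @param seed integer seed (used when `noise = TRUE`).
#' @param noise draw Poisson counts (`TRUE`) or round the expectation.
#' @param quantize with `noise = FALSE`, round the expectation to integer
#'   counts (the default, matching real photon histograms).
#'   `quantize = FALSE` keeps the exact expectation: rounding is a
#'   deterministic distortion, not noise, and near-background channels
#'   quantized to a staircase bias model-validation round trips along the
#'   shallow k_PT--k_a ridge, so self-consistency fits use the exact
#'   expectation.
#' @return object of class `tcspc_histogram` with `counts` (integer
#'   unless `quantize = FALSE`), channel `times` and the paired `irf`.
#' @export
make_tcspc <- function(curve, irf, peak_counts = 1e4, background = 1,
                       seed = 1L, noise = TRUE, quantize = TRUE) {
  if (length(curve$times) != length(irf$times) ||
      max(abs(curve$times - irf$times)) > 1e-9)
    pa_stop("invalid_argument", "curve and IRF must share one channel grid")
  if (!is.finite(peak_counts) || peak_counts < 1)
    pa_stop("invalid_argument", "peak_counts must be >= 1")
  if (background < 0 || background >= peak_counts)
    pa_stop("invalid_argument", "background must be in [0, peak_counts)")
  conv <- causal_convolve(curve$intensity, irf$weights)
  mx <- max(conv)
  if (mx <= 0)
    pa_stop("invalid_argument", "curve convolves to zero intensity")
  lambda <- conv / mx * (peak_counts - background) + background
  counts <- if (noise) as.integer(with_seed(seed, rpois(length(lambda), lambda)))
            else if (quantize) as.integer(round(lambda))
            else lambda
  structure(
    list(times = curve$times, counts = counts, irf = irf,
         meta = list(peak_target = peak_counts, background = background,
                     seed = if (noise) seed else NA_integer_,
                     noise = noise, quantize = quantize || noise)),
    class = "tcspc_histogram")
}

#' @export
print.tcspc_histogram <- function(x, ...) {
  cat(sprintf("<tcspc_histogram> %d channels x %g ns, peak = %d counts%s\n",
              length(x$times), x$times[2] - x$times[1], max(x$counts),
              if (isTRUE(x$meta$noise)) sprintf(" (Poisson, seed %d)",
                                                x$meta$seed) else ""))
  invisible(x)
}

#' Synthesise the full decay for one photoacid and condition
#'
#' Convenience wrapper chaining [solve_dse()],
#' [apply_excited_state_decay()] and [make_tcspc()] on the standard
#' 0-200 ns, 0.055 ns/channel TCSPC window with the ~1 ns FWHM IRF.
#'
#' @param config a [solver_config()] (e.g. from [photoacid_registry()]).
#' @param irf the IRF; default [gaussian_irf()].
#' @param tau_roh ROH* lifetime, ns.
#' @param peak_counts,background,seed,noise,quantize passed to
#'   [make_tcspc()].
#' @param grid optional [grid_spec()] override.
#' @return a `tcspc_histogram`.
#' @export
synth_decay <- function(config, irf = gaussian_irf(), tau_roh = 8,
                        peak_counts = 1e4, background = 1, seed = 1L,
                        noise = FALSE, quantize = TRUE, grid = NULL) {
  times <- irf$times
  if (is.null(grid))
    grid <- grid_spec(t_max = max(times), output_times = times,
                      n_r = 400L, dt_max = max(times) / 400)
  tr <- solve_dse(config, grid)
  curve <- apply_excited_state_decay(tr, tau_roh = tau_roh)$roh
  make_tcspc(curve, irf, peak_counts = peak_counts,
             background = background, seed = seed, noise = noise,
             quantize = quantize)
}

#' Amyloidogenesis trace of the RO-*/ROH* ratio
#'
#' Logistic interpolation between the free-photoacid ratio and the
#' fibril-bound ratio, emulating the sigmoidal aggregation kinetics of
#' insulin: a lag phase, exponential growth, and a stationary plateau.
#' The inflection sits at `t50 = lag_min + 2/rate_per_min` (the usual
#' lag-time convention: the tangent at the inflection intercepts the
#' baseline at `lag_min`).
#'
#' @param ratio_free,ratio_bound plateau ratios before and after
#'   fibrillisation.
#' @param lag_min lag time, minutes (>= 0).
#' @param rate_per_min logistic growth rate, 1/min (> 0).
#' @param times sampling times, minutes.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return object of class `amyloid_trace` with `times`, `ratio`, and
#'   the generator parameters.
#' @export
amyloid_trace <- function(ratio_free, ratio_bound, lag_min = 60,
                          rate_per_min = 0.1, times = seq(0, 180, by = 20),
                          noise_sd = 0, seed = 1L) {
  stopifnot_finite(c(ratio_free, ratio_bound, lag_min, rate_per_min),
                   "trace parameters")
  if (lag_min < 0) pa_stop("invalid_argument", "lag_min must be >= 0")
  if (rate_per_min <= 0) pa_stop("invalid_argument", "rate_per_min must be > 0")
  t50 <- lag_min + 2 / rate_per_min
  ratio <- ratio_bound + (ratio_free - ratio_bound) /
    (1 + exp(rate_per_min * (times - t50)))
  if (noise_sd > 0)
    ratio <- ratio + with_seed(seed, rnorm(length(times), 0, noise_sd))
  structure(
    list(times = times, ratio = ratio,
         params = list(ratio_free = ratio_free, ratio_bound = ratio_bound,
                       lag_min = lag_min, rate_per_min = rate_per_min,
                       t50 = t50, noise_sd = noise_sd, seed = seed)),
    class = "amyloid_trace")
}

#' Fit logistic aggregation kinetics to a ratio trace
#'
#' Bounded Levenberg-Marquardt fit of the 4-parameter logistic
#' (two plateaus, inflection time `t50`, rate), reporting the lag time
#' `t50 - 2/rate` and approximate standard errors.  A trace whose two
#' plateaus are indistinguishable is flagged `rate_unidentifiable`; a
#' trace whose residuals show systematic non-monotone structure beyond
#' the noise is flagged `poor_fit`.
#'
#' @param trace an [amyloid_trace()] (or list with `times`, `ratio`).
#' @return list with `lag_min`, `rate_per_min`, `t50`, `ratio_free`,
#'   `ratio_bound`, `se` (named), and flags.
#' @export
fit_amyloid_kinetics <- function(trace) {
  t <- trace$times
  y <- trace$ratio
  if (length(t) < 6)
    pa_stop("invalid_argument", "need >= 6 time points")
  span <- max(y) - min(y)
  resid_scale <- sd(diff(y)) / sqrt(2)
  if (span < max(1e-8, 2 * resid_scale))
    return(list(lag_min = NA_real_, rate_per_min = NA_real_,
                t50 = NA_real_, ratio_free = mean(y), ratio_bound = mean(y),
                se = NULL, rate_unidentifiable = TRUE, poor_fit = FALSE))
  y0 <- y[1]; y1 <- y[length(y)]
  t50_0 <- t[which.min(abs(y - (y0 + y1) / 2))]
  k0 <- 8 / (max(t) - min(t))
  fn <- function(p) {
    y1h <- p[1]; y0h <- p[2]; t50 <- p[3]; k <- p[4]
    y - (y1h + (y0h - y1h) / (1 + exp(k * (t - t50))))
  }
  fit <- minpack.lm::nls.lm(
    par = c(y1, y0, t50_0, k0), fn = fn,
    lower = c(-Inf, -Inf, min(t) - diff(range(t)), 1e-6),
    upper = c(Inf, Inf, max(t) + diff(range(t)), 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) *
                        fit$deviance / max(1, length(t) - 4)),
                 error = function(e) rep(NA_real_, 4))
  res <- fn(p)
  poor <- sd(res) > max(3 * resid_scale, 0.02 * span)
  list(lag_min = p[3] - 2 / p[4], rate_per_min = p[4], t50 = p[3],
       ratio_free = p[2], ratio_bound = p[1],
       se = setNames(se, c("ratio_bound", "ratio_free", "t50", "rate")),
       rate_unidentifiable = FALSE, poor_fit = poor)
}
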