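#' Emission curve
#'
#' Time-resolved relative emission intensity of one photoacid species.
#'
#' @param times strictly increasing times, ns.
#' @param intensity non-negative relative intensities.
#' @param species `"ROH*"` or `"RO-*"`.
#' @return object of class `emission_curve`.
#' @export
emission_curve <- function(times, intensity, species = c("ROH*", "RO-*")) {
  species <- match.arg(species)
  stopifnot_finite(times, "times")
  stopifnot_finite(intensity, "intensity")
  if (length(times) != length(intensity))
    pa_stop("invalid_argument", "times and intensity lengths differ")
  if (is.unsorted(times, strictly = TRUE))
    pa_stop("invalid_argument", "times must be strictly increasing")
  if (any(intensity < 0))
    pa_stop("invalid_argument", "intensity must be non-negative")
  structure(list(times = times, intensity = intensity, species = species),
            class = "emission_curve")
}

#' Weight solver populations by the excited-state radiative lifetimes
#'
#' The solver conserves probability (no radiative decay inside it); the
#' observable fluorescence applies the lifetimes multiplicatively:
#' `I_ROH(t) = P_bound(t) exp(-t/tau_roh)` and
#' `I_RO(t) = (1 - P_bound(t)) exp(-t/tau_ro)`.
#'
#' @param trace a `kinetic_trace` from [solve_dse()].
#' @param tau_roh,tau_ro excited-state lifetimes in ns (> 0; `Inf`
#'   returns the raw populations).
#' @return list with `emission_curve` elements `roh` and `ro`.
#' @export
apply_excited_state_decay <- function(trace, tau_roh = 8, tau_ro = 10) {
  if (!inherits(trace, "kinetic_trace"))
    pa_stop("invalid_argument", "trace must be a kinetic_trace")
  if (tau_roh <= 0 || tau_ro <= 0)
    pa_stop("invalid_argument", "lifetimes must be > 0")
  t <- trace$times
  list(
    roh = emission_curve(t, trace$p_bound * exp(-t / tau_roh), "ROH*"),
    ro = emission_curve(t, trace$separated_fraction * exp(-t / tau_ro),
                        "RO-*"))
}

#' Gaussian instrument response function
#'
#' Discretised Gaussian IRF on a uniform channel grid, normalized to unit
#' sum.  The default emulates a ~1 ns FWHM LED excitation pulse sampled
#' at 0.055 ns per channel.
#'
#' @param fwhm full width at half maximum, ns.
#' @param t0 pulse centre, ns (needs `t0 >= 3 sigma` for causal support).
#' @param channel_width channel width, ns.
#' @param n_channels number of channels.
#' @return object of class `irf` with `times`, unit-sum `weights`,
#'   `fwhm` and `t0`.
#' @export
gaussian_irf <- function(fwhm = 1, t0 = 5, channel_width = 0.055,
                         n_channels = 3636L) {
  stopifnot_finite(c(fwhm, t0, channel_width), "fwhm, t0, channel_width")
  if (fwhm <= 0) pa_stop("invalid_argument", "fwhm must be > 0")
  if (fwhm < 2 * channel_width)
    pa_stop("under_resolved_irf",
            "fwhm = %g ns under-resolved at channel width %g ns",
            fwhm, channel_width)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (t0 < 3 * sigma || t0 > (n_channels - 1) * channel_width)
    pa_stop("invalid_argument", "t0 must give causal support inside the window")
  times <- (seq_len(n_channels) - 1) * channel_width
  w <- dnorm(times, mean = t0, sd = sigma)
  w <- w / sum(w)
  structure(list(times = times, weights = w, fwhm = fwhm, t0 = t0,
                 channel_width = channel_width),
            class = "irf")
}

#' @export
print.irf <- function(x, ...) {
  cat(sprintf("<irf> fwhm = %g ns at t0 = %g ns; %d channels of %g ns\n",
              x$fwhm, x$t0, length(x$times), x$channel_width))
  invisible(x)
}

#' Causal convolution of an emission curve with an IRF
#'
#' Discrete causal convolution on a shared uniform channel grid:
#' `y[k] = sum_j irf[j] x[k - j + 1]`.  With a unit-sum IRF the total
#' intensity inside the window is preserved up to the convolved tail that
#' leaves it.
#'
#' @param curve an [emission_curve()] (or any list with `times`,
#'   `intensity`).
#' @param irf an [gaussian_irf()] object on the same grid.
#' @return an `emission_curve` on the same grid.
#' @export
convolve_irf <- function(curve, irf) {
  if (length(curve$times) != length(irf$times) ||
      max(abs(curve$times - irf$times)) > 1e-9)
    pa_stop("invalid_argument", "curve and IRF must share one channel grid")
  y <- causal_convolve(curve$intensity, irf$weights)
  emission_curve(curve$times, pmax(y, 0),
                 if (!is.null(curve$species)) curve$species else "ROH*")
}

# FFT-based causal convolution, first n samples of the full product
# (zero-padded to a power of two for fast transforms)
causal_convolve <- function(x, w) {
  n <- length(x)
  L <- 2^ceiling(log2(2 * n))
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                       stats::fft(c(w, numeric(L - n))), inverse = TRUE)) / L
  y[seq_len(n)]
}

#' Two-band spectral model
#'
#' Gaussian ROH* and RO-* emission bands on the wavelength axis.  Widths
#' are Gaussian standard deviations in nm.  An optional bathochromic
#' shift displaces the RO-* band to the red (as observed upon binding to
#' a less polar fibril surface).
#'
#' @param roh_center,ro_center band centres, nm (`ro_center` must be to
#'   the red of `roh_center`).
#' @param roh_width,ro_width Gaussian standard deviations, nm (> 0).
#' @param bathochromic_shift_nm shift added to the RO-* centre, nm.
#' @return object of class `band_model`.
#' @export
band_model <- function(roh_center = 355, ro_center = 420,
                       roh_width = 20, ro_width = 20,
                       bathochromic_shift_nm = 0) {
  stopifnot_finite(c(roh_center, ro_center, roh_width, ro_width,
                     bathochromic_shift_nm), "band parameters")
  if (roh_width <= 0 || ro_width <= 0)
    pa_stop("invalid_argument", "band widths must be > 0")
  if (ro_center <= roh_center)
    pa_stop("invalid_argument", "ro_center must exceed roh_center")
  structure(list(roh_center = roh_center,
                 ro_center = ro_center + bathochromic_shift_nm,
                 roh_width = roh_width, ro_width = ro_width),
            class = "band_model")
}

band_matrix <- function(bands, wavelengths) {
  cbind(roh = dnorm(wavelengths, bands$roh_center, bands$roh_width),
        ro = dnorm(wavelengths, bands$ro_center, bands$ro_width))
}

#' Steady-state emission spectrum
#'
#' @param wavelengths strictly increasing wavelengths, nm.
#' @param intensity non-negative relative intensities.
#' @return object of class `steady_spectrum`.
#' @export
steady_spectrum <- function(wavelengths, intensity) {
  stopifnot_finite(wavelengths, "wavelengths")
  stopifnot_finite(intensity, "intensity")
  if (length(wavelengths) != length(intensity))
    pa_stop("invalid_argument", "wavelengths and intensity lengths differ")
  if (is.unsorted(wavelengths, strictly = TRUE))
    pa_stop("invalid_argument", "wavelengths must be strictly increasing")
  if (any(intensity < 0))
    pa_stop("invalid_argument", "intensity must be non-negative")
  structure(list(wavelengths = wavelengths, intensity = intensity),
            class = "steady_spectrum")
}

#' Synthesise a two-band steady-state spectrum
#'
#' Sum of two unit-area Gaussian bands with RO-*/ROH* band-area ratio
#' `ratio`; [measure_ratio()] applied to the result returns `ratio`.
#'
#' @param ratio RO-*/ROH* band-area ratio (>= 0).
#' @param bands a [band_model()].
#' @param wavelengths wavelength grid, nm; must cover both band centres.
#' @return a [steady_spectrum()].
#' @examples
#' sp <- synth_spectrum(48.5, band_model(roh_center = 370))
#' measure_ratio(sp, band_model(roh_center = 370))
#' @export
synth_spectrum <- function(ratio, bands, wavelengths = seq(300, 550, by = 1)) {
  stopifnot_finite(ratio, "ratio")
  if (ratio < 0) pa_stop("invalid_argument", "ratio must be >= 0")
  if (!inherits(bands, "band_model"))
    pa_stop("invalid_argument", "bands must be a band_model")
  if (bands$roh_center < min(wavelengths) ||
      bands$ro_center > max(wavelengths))
    pa_stop("invalid_argument", "band centres must lie inside the grid")
  B <- band_matrix(bands, wavelengths)
  steady_spectrum(wavelengths, B[, "roh"] + ratio * B[, "ro"])
}

#' Measure the RO-*/ROH* ratio of a spectrum
#'
#' Non-negative least-squares unmixing of a spectrum into the two bands
#' of a [band_model()]; returns the RO-*/ROH* band-area ratio (bands are
#' unit-area, so the amplitude ratio is the area ratio).  Scale-invariant
#' in the spectrum.  `mode = "peak"` converts to the peak-height ratio.
#'
#' @param spectrum a [steady_spectrum()] covering both band centres.
#' @param bands a [band_model()].
#' @param mode `"area"` (default) or `"peak"`.
#' @return non-negative ratio (may be `Inf` when the ROH* band amplitude
#'   is zero).
#' @export
measure_ratio <- function(spectrum, bands, mode = c("area", "peak")) {
  mode <- match.arg(mode)
  if (!inherits(spectrum, "steady_spectrum"))
    pa_stop("invalid_argument", "spectrum must be a steady_spectrum")
  wl <- spectrum$wavelengths
  if (bands$roh_center < min(wl) || bands$ro_center > max(wl))
    pa_stop("invalid_argument", "spectrum must cover both band centres")
  if (abs(bands$roh_center - bands$ro_center) < 1e-9 &&
      abs(bands$roh_width - bands$ro_width) < 1e-9)
    pa_stop("unidentifiable_model", "identical bands cannot be unmixed")
  B <- band_matrix(bands, wl)
  beta <- nnls2(B, spectrum$intensity)
  ratio <- if (beta[1] == 0 && beta[2] == 0) 0
           else if (beta[1] == 0) Inf
           else beta[2] / beta[1]
  if (mode == "peak" && is.finite(ratio) && ratio > 0)
    ratio <- ratio * bands$roh_width / bands$ro_width
  ratio
}

# two-column non-negative least squares (exact active-set enumeration)
nnls2 <- function(B, y) {
  fit2 <- tryCatch(qr.solve(crossprod(B), crossprod(B, y)),
                   error = function(e) c(-1, -1))
  if (all(fit2 >= 0)) return(as.numeric(fit2))
  b1 <- max(0, sum(B[, 1] * y) / sum(B[, 1]^2))
  b2 <- max(0, sum(B[, 2] * y) / sum(B[, 2]^2))
  rss <- function(b) sum((y - B %*% b)^2)
  cands <- list(c(b1, 0), c(0, b2))
  cands[[which.min(vapply(cands, rss, numeric(1)))]]
}
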