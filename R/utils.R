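# internal helpers: classed conditions and seed scoping

pa_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("photoacid_", class), "photoacid_error")))
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    pa_stop("invalid_argument", "%s must be finite numeric", what)
}

# Evaluate `code` with a private RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards, so generators are pure in (args, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    pa_stop("invalid_argument", "seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# complementary error function via the normal CDF
erfc <- function(x) 2 * pnorm(-sqrt(2) * x)

# log-log natural-spline interpolation for smooth positive decays;
# falls back to linear interpolation when values are not strictly positive.
interp_decay <- function(t_in, y_in, t_out) {
  out <- numeric(length(t_out))
  zero <- t_out <= 0
  if (any(zero)) out[zero] <- y_in[1L]
  pos <- !zero
  if (!any(pos)) return(out)
  ti <- t_in[t_in > 0]
  yi <- y_in[t_in > 0]
  if (all(yi > 0) && length(ti) > 4) {
    out[pos] <- exp(spline(log(ti), log(yi), xout = log(t_out[pos]),
                           method = "natural")$y)
  } else {
    out[pos] <- approx(t_in, y_in, xout = t_out[pos], rule = 2)$y
  }
  out
}
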