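#' Dielectric medium context
#'
#' Bundles the medium properties entering the Debye radius: the relative
#' dielectric permittivity and the absolute temperature, together with the
#' CODATA values of the elementary charge, vacuum permittivity and
#' Boltzmann constant.  The default is water at 20 degrees C
#' (`epsilon_r = 80.1`, `T = 293.15` K), the medium of the buffered
#' photoacid measurements.
#'
#' @param relative_permittivity dimensionless relative permittivity
#'   (epsilon_r > 0).
#' @param temperature_K absolute temperature in kelvin (> 0).
#' @return An object of class `medium_context`.
#' @examples
#' medium_context()                  # water at 20 C
#' medium_context(6, 293.15)         # a low-permittivity protein pocket
#' @export
medium_context <- function(relative_permittivity = 80.1,
                           temperature_K = 293.15) {
  stopifnot_finite(relative_permittivity, "relative_permittivity")
  stopifnot_finite(temperature_K, "temperature_K")
  if (relative_permittivity <= 0 || temperature_K <= 0)
    pa_stop("invalid_argument",
            "relative_permittivity and temperature_K must be positive")
  structure(
    list(relative_permittivity = relative_permittivity,
         temperature_K = temperature_K,
         e_C = 1.602176634e-19,        # elementary charge [C]
         eps0_F_per_m = 8.8541878128e-12,  # vacuum permittivity [F/m]
         kB_J_per_K = 1.380649e-23),   # Boltzmann constant [J/K]
    class = "medium_context")
}

#' @export
print.medium_context <- function(x, ...) {
  cat(sprintf("<medium_context> eps_r = %g, T = %g K\n",
              x$relative_permittivity, x$temperature_K))
  invisible(x)
}

#' Debye radius of an ion pair
#'
#' Distance at which the Coulomb attraction between two ions of `z1` and
#' `z2` elementary charges equals the thermal energy:
#' `R_D = |Z1 Z2| e^2 / (4 pi eps0 eps_r kB T)`.  For the photoacids this
#' is the attraction between the dissociated RO-* anion and the geminate
#' proton.  Exactly linear in `|Z1 Z2|` and inversely proportional to both
#' the permittivity and the temperature.
#'
#' @param z1,z2 integer charges in elementary-charge units (0 allowed).
#' @param medium a [medium_context()].
#' @return Debye radius in angstrom.
#' @examples
#' debye_radius(1, 1)   # 2-naphthol anion + proton in water: ~7 A
#' debye_radius(3, 1)   # the 6,8-disulfonate dianion-phenolate: ~21 A
#' @export
debye_radius <- function(z1, z2, medium = medium_context()) {
  stopifnot_finite(z1, "z1")
  stopifnot_finite(z2, "z2")
  if (any(abs(c(z1, z2) - round(c(z1, z2))) > 1e-8))
    pa_stop("invalid_argument", "z1 and z2 must be integer charge numbers")
  if (!inherits(medium, "medium_context"))
    pa_stop("invalid_argument", "medium must be a medium_context")
  m <- medium
  r_m <- abs(z1 * z2) * m$e_C^2 /
    (4 * pi * m$eps0_F_per_m * m$relative_permittivity *
       m$kB_J_per_K * m$temperature_K)
  r_m * 1e10  # m -> angstrom
}
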