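#' @keywords internal
.check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= 0) {
    stop(sprintf("'%s' must be strictly positive (got %g)", name, x),
         call. = FALSE)
  }
  if (!strict && x < 0) {
    stop(sprintf("'%s' must be non-negative (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
.check_positive_vec <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

#' Nanoparticle specification
#'
#' Describes a spherical nanoparticle by its diameter and solid density.
#' All quantities are SI: metres and kg/m^3.
#'
#' @param name Short label, e.g. `"nanoAg"`.
#' @param d Particle diameter in metres (e.g. `9e-9` for 9 nm).
#' @param rho_s Solid density of the particle material in kg/m^3.
#'
#' @return An object of class `particle_spec`.
#' @examples
#' particle_spec("nanoAg", d = 9e-9, rho_s = 7874)
#' @export
particle_spec <- function(name, d, rho_s) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_positive(d, "d")
  .check_positive(rho_s, "rho_s")
  structure(list(name = name, d = d, rho_s = rho_s), class = "particle_spec")
}

#' Transport medium specification
#'
#' The continuous fluid phase through which particles diffuse: temperature,
#' dynamic viscosity and density. For skin scenarios the viscosity is that of
#' the intercellular cement.
#'
#' @param T Absolute temperature in kelvin.
#' @param mu Dynamic viscosity in Pa*s.
#' @param rho_c Fluid density in kg/m^3.
#'
#' @return An object of class `medium_spec`.
#' @examples
#' water20 <- medium_spec(T = 293.15, mu = 0.001, rho_c = 1000)
#' @export
medium_spec <- function(T = 293.15, mu = 0.001, rho_c = 1000) {
  .check_positive(T, "T")
  .check_positive(mu, "mu")
  .check_positive(rho_c, "rho_c")
  structure(list(T = T, mu = mu, rho_c = rho_c), class = "medium_spec")
}

#' Franz-cell process conditions
#'
#' Geometry and operating conditions of a diffusion-cell run: exchange
#' cross-section, chamber volume, duration and initial donor concentration.
#' Concentration is in g/m^3, numerically equal to mg/L.
#'
#' @param A Exchange cross-section area in m^2.
#' @param V Liquid volume per chamber in m^3.
#' @param t Process duration in seconds.
#' @param c0 Initial donor concentration in g/m^3 (= mg/L).
#'
#' @return An object of class `cell_conditions`.
#' @examples
#' # the membrane study: 2 cm diameter window, 10 mL chambers, 12 h, 400 mg/L
#' franz <- cell_conditions(A = 3.14e-4, V = 1e-5, t = 43200, c0 = 400)
#' @export
cell_conditions <- function(A, V, t, c0) {
  .check_positive(A, "A")
  .check_positive(V, "V")
  .check_positive(t, "t")
  .check_positive(c0, "c0")
  structure(list(A = A, V = V, t = t, c0 = c0), class = "cell_conditions")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> %s: d = %g nm, rho_s = %g kg/m^3\n",
              x$name, x$d * 1e9, x$rho_s))
  invisible(x)
}

#' @export
print.medium_spec <- function(x, ...) {
  cat(sprintf("<medium_spec> T = %g K, mu = %g Pa.s, rho_c = %g kg/m^3\n",
              x$T, x$mu, x$rho_c))
  invisible(x)
}

#' @export
print.cell_conditions <- function(x, ...) {
  cat(sprintf(
    "<cell_conditions> A = %g cm^2, V = %g mL, t = %g h, c0 = %g mg/L\n",
    x$A * 1e4, x$V * 1e6, x$t / 3600, x$c0))
  invisible(x)
}
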