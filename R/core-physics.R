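# Closed-form transport physics for nanoparticles crossing a layered barrier:
# Stokes-Einstein diffusion, Stokes sedimentation, steady-state Fick-flux
# bookkeeping and the quasi-steady permeated-mass closed form.
#
# Units are SI throughout: metres, seconds, kelvin, Pa*s, g/m^3 (= mg/L) for
# concentration and grams for mass.

#' Physical constants
#'
#' Boltzmann constant (CODATA) and standard gravity used by the closed forms.
#' @keywords internal
#' @name constants
BOLTZMANN <- 1.380649e-23 # J/K
GRAVITY <- 9.81           # m/s^2

#' Stokes-Einstein diffusion coefficient
#'
#' Free-liquid diffusivity of a spherical particle,
#' `D = kB * T / (6 * pi * mu * d)`.
#'
#' @param particle A [particle_spec()].
#' @param medium A [medium_spec()].
#'
#' @return Diffusivity in m^2/s.
#' @examples
#' nanoAg <- particle_spec("nanoAg", d = 9e-9, rho_s = 7874)
#' diffusion_coefficient(nanoAg, medium_spec(T = 293.15, mu = 0.001))
#' @export
diffusion_coefficient <- function(particle, medium) {
  stopifnot(inherits(particle, "particle_spec"), inherits(medium, "medium_spec"))
  BOLTZMANN * medium$T / (6 * pi * medium$mu * particle$d)
}

#' Stokes sedimentation velocity
#'
#' Terminal settling velocity in the laminar (Stokes) regime,
#' `u0 = d^2 * g * (rho_s - rho_c) / (18 * mu)`. Negative for buoyant
#' particles (`rho_s < rho_c`).
#'
#' @inheritParams diffusion_coefficient
#'
#' @return Velocity in m/s.
#' @export
sedimentation_velocity <- function(particle, medium) {
  stopifnot(inherits(particle, "particle_spec"), inherits(medium, "medium_spec"))
  particle$d^2 * GRAVITY * (particle$rho_s - medium$rho_c) / (18 * medium$mu)
}

#' Distance covered by a sedimenting particle
#'
#' @param u0 Sedimentation velocity in m/s.
#' @param t Time in seconds, non-negative.
#'
#' @return Distance `u0 * t` in metres.
#' @export
sedimentation_distance <- function(u0, t) {
  stopifnot(is.numeric(u0), is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  u0 * t
}

#' Diffusive mass flux from permeated mass
#'
#' `J = m_p / (A * t)`: mass that crossed a window of area `A` in time `t`.
#'
#' @param m_p Permeated mass in grams, non-negative.
#' @param A Exchange area in m^2, strictly positive.
#' @param t Duration in seconds, strictly positive.
#'
#' @return Flux in g/(m^2*s).
#' @export
mass_flux <- function(m_p, A, t) {
  if (any(m_p < 0)) stop("'m_p' must be non-negative", call. = FALSE)
  .check_positive_vec(A, "A")
  .check_positive_vec(t, "t")
  m_p / (A * t)
}

#' Effective diffusivity from a measured acceptor concentration
#'
#' Inverts the steady-state Fick relation for a Franz-cell run. With
#' `m_p = c_p * V` and `J = m_p/(A*t) = D_ef * (c0 - c_p)/L`,
#' `D_ef = c_p * V * L / (A * t * (c0 - c_p))`.
#' Exact algebraic inverse of [acceptor_concentration()].
#'
#' @param c_p Measured acceptor concentration in g/m^3; must satisfy
#'   `0 <= c_p < c0`.
#' @param cond A [cell_conditions()].
#' @param L Barrier thickness in metres.
#'
#' @return Effective diffusivity in m^2/s.
#' @export
effective_diffusivity <- function(c_p, cond, L) {
  stopifnot(inherits(cond, "cell_conditions"))
  .check_positive_vec(L, "L")
  if (any(c_p < 0)) stop("'c_p' must be non-negative", call. = FALSE)
  if (any(c_p >= cond$c0)) {
    stop("steady-state assumption violated: c_p >= c0", call. = FALSE)
  }
  c_p * cond$V * L / (cond$A * cond$t * (cond$c0 - c_p))
}

#' Acceptor concentration predicted from an effective diffusivity
#'
#' Forward form of the quasi-steady model: with `c_p = m_p / V`,
#' `c_p = D_ef * A * t * c0 / (V * L + D_ef * A * t)`, always in `[0, c0)`.
#'
#' @param D_ef Effective diffusivity in m^2/s, non-negative.
#' @inheritParams effective_diffusivity
#'
#' @return Acceptor concentration in g/m^3.
#' @export
acceptor_concentration <- function(D_ef, cond, L) {
  stopifnot(inherits(cond, "cell_conditions"))
  .check_positive_vec(L, "L")
  if (any(D_ef < 0)) stop("'D_ef' must be non-negative", call. = FALSE)
  D_ef * cond$A * cond$t * cond$c0 / (cond$V * L + D_ef * cond$A * cond$t)
}

#' Retardation coefficient
#'
#' `a = D_ef / D`: how much a barrier slows diffusion relative to the free
#' liquid. Values in (0, 1] are physical; `a > 1` (possible with noisy
#' measurements) triggers a warning, not an error.
#'
#' @param D_ef Effective diffusivity in m^2/s.
#' @param D Free-liquid diffusivity in m^2/s, strictly positive.
#'
#' @return Dimensionless retardation coefficient.
#' @export
retardation_coefficient <- function(D_ef, D) {
  if (any(D <= 0)) stop("'D' must be strictly positive", call. = FALSE)
  if (any(D_ef < 0)) stop("'D_ef' must be non-negative", call. = FALSE)
  if (any(D_ef > D)) {
    warning("D_ef > D: retardation coefficient exceeds 1", call. = FALSE)
  }
  D_ef / D
}

#' Permeated nanoparticle mass (quasi-steady closed form)
#'
#' `m_p = D_ef * c0 / (L/(A*t) + D_ef/V)`. Bounded above by the initial mass
#' `m_0 = c0 * V`, strictly increasing in `D_ef`, and tends to `m_0` as
#' `L -> 0`. Evaluated once per scenario; no back-diffusion correction.
#'
#' @inheritParams acceptor_concentration
#'
#' @return Permeated mass in grams.
#' @export
permeated_mass <- function(D_ef, cond, L) {
  stopifnot(inherits(cond, "cell_conditions"))
  .check_positive_vec(L, "L")
  if (any(D_ef < 0)) stop("'D_ef' must be non-negative", call. = FALSE)
  D_ef * cond$c0 / (L / (cond$A * cond$t) + D_ef / cond$V)
}
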