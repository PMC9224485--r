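# End-to-end forward prediction: barrier geometry -> Y -> retardation ->
# effective diffusivity -> permeated mass, for filter stacks and for the
# brick-wall stratum corneum swept over layer count.

#' Skin permeation scenario
#'
#' Bundles everything needed to predict nanoparticle permeation through a
#' brick-wall stratum corneum: geometry, particle, medium (whose viscosity is
#' that of the intercellular cement), process conditions, the adsorption
#' model constant k, and the dimensionless mass cut-off used for penetration
#' limits.
#'
#' The default conditions describe a 1 cm^2 exchange area, a 0.2 cm^3 donor
#' volume (a 2 mm film of solution over the skin), c0 = 10 g/L and a 12 h
#' exposure, with a 9 nm particle and k = 0.3884 (the hydrophilic-filter
#' fit).
#'
#' @param geometry A [brick_geometry()].
#' @param particle A [particle_spec()].
#' @param medium A [medium_spec()]; `mu` is the cement viscosity.
#' @param conditions A [cell_conditions()].
#' @param k Adsorption model constant, non-negative.
#' @param threshold Dimensionless `m_p/m_0` cut-off in (0, 1) below which
#'   transport is considered not to occur (default 0.005).
#'
#' @return An object of class `skin_scenario`.
#' @examples
#' sc <- skin_scenario()
#' penetration_limit(sc)  # 344 layers at cement viscosity 0.001 Pa.s
#' @export
skin_scenario <- function(geometry = brick_geometry(),
                          particle = particle_spec("nanoAg", 9e-9, 7874),
                          medium = medium_spec(T = 293.15, mu = 0.001,
                                               rho_c = 1000),
                          conditions = cell_conditions(A = 1e-4, V = 0.2e-6,
                                                       t = 43200, c0 = 1e4),
                          k = 0.3884, threshold = 0.005) {
  stopifnot(inherits(geometry, "brick_geometry"),
            inherits(particle, "particle_spec"),
            inherits(medium, "medium_spec"),
            inherits(conditions, "cell_conditions"))
  if (k < 0) stop("'k' must be non-negative", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  }
  structure(list(geometry = geometry, particle = particle, medium = medium,
                 conditions = conditions, k = k, threshold = threshold),
            class = "skin_scenario")
}

#' @export
print.skin_scenario <- function(x, ...) {
  cat("<skin_scenario>\n")
  cat(sprintf("  particle: %s, d = %g nm\n", x$particle$name,
              x$particle$d * 1e9))
  cat(sprintf("  cement viscosity: %g Pa.s, T = %g K\n", x$medium$mu,
              x$medium$T))
  cat(sprintf("  layer pitch: %g um, Y per layer: %.3f\n",
              (x$geometry$x_k + x$geometry$x_c) * 1e6,
              brick_layer_surface_parameter(x$geometry)))
  cat(sprintf("  k = %g, threshold m_p/m_0 = %g\n", x$k, x$threshold))
  invisible(x)
}

#' Cumulative surface parameter at a continuous depth
#'
#' Depth is discretised in whole layers; for a continuous depth query the
#' cumulative Y interpolates linearly, `Y(L) = L/(x_k + x_c) * Y_layer`.
#'
#' @param scenario A [skin_scenario()].
#' @param L Depth in metres.
#'
#' @return Cumulative dimensionless surface parameter.
#' @export
depth_surface_parameter <- function(scenario, L) {
  stopifnot(inherits(scenario, "skin_scenario"))
  if (any(L < 0)) stop("'L' must be non-negative", call. = FALSE)
  pitch <- scenario$geometry$x_k + scenario$geometry$x_c
  L / pitch * brick_layer_surface_parameter(scenario$geometry)
}

#' Permeation profile over brick layers
#'
#' For each layer count `N = 1..N_max`: depth `L = N*(x_k + x_c)`, cumulative
#' surface parameter `Y = N*Y_layer`, retardation `a = 1/(1 + k*Y)`,
#' effective diffusivity `D_ef = a*D`, and the permeated mass from the
#' quasi-steady closed form, together with the dimensionless mass
#' `m_ratio = m_p/(c0*V)`.
#'
#' @param scenario A [skin_scenario()].
#' @param N_max Largest layer count to evaluate.
#'
#' @return A data frame of class `penetration_profile` with columns `N`, `L`
#'   (m), `Y`, `a`, `D_ef` (m^2/s), `m_p` (g), `m_ratio`.
#' @examples
#' prof <- permeation_profile(skin_scenario(), N_max = 50)
#' head(prof, 3)
#' @export
permeation_profile <- function(scenario, N_max = 500L) {
  stopifnot(inherits(scenario, "skin_scenario"))
  N_max <- as.integer(N_max)
  if (N_max < 1L) stop("'N_max' must be at least 1", call. = FALSE)
  N <- seq_len(N_max)
  g <- scenario$geometry
  Y_layer <- brick_layer_surface_parameter(g)
  D <- diffusion_coefficient(scenario$particle, scenario$medium)
  L <- N * (g$x_k + g$x_c)
  Y <- N * Y_layer
  a <- retention_fraction(Y, scenario$k)
  D_ef <- a * D
  m_p <- permeated_mass(D_ef, scenario$conditions, L)
  m_0 <- scenario$conditions$c0 * scenario$conditions$V
  out <- data.frame(N = N, L = L, Y = Y, a = a, D_ef = D_ef, m_p = m_p,
                    m_ratio = m_p / m_0)
  class(out) <- c("penetration_profile", "data.frame")
  attr(out, "scenario") <- scenario
  out
}

#' Penetration limit: deepest layer still passing mass
#'
#' The largest layer count `N` whose dimensionless permeated mass
#' `m_p/m_0` still meets the scenario threshold (boundary included); 0 if
#' even the first layer falls below it. `m_ratio` decreases strictly with
#' `N`, so an ascending scan terminates at the first failing layer.
#'
#' @param scenario A [skin_scenario()].
#' @param N_max Scan ceiling; an error is raised if the threshold is still
#'   met there, since the limit would be censored.
#'
#' @return Integer layer count `N_L`.
#' @examples
#' penetration_limit(skin_scenario())  # 344
#' @export
penetration_limit <- function(scenario, N_max = 100000L) {
  stopifnot(inherits(scenario, "skin_scenario"))
  g <- scenario$geometry
  Y_layer <- brick_layer_surface_parameter(g)
  D <- diffusion_coefficient(scenario$particle, scenario$medium)
  cond <- scenario$conditions
  m_0 <- cond$c0 * cond$V
  pitch <- g$x_k + g$x_c

  ratio_at <- function(N) {
    a <- retention_fraction(N * Y_layer, scenario$k)
    permeated_mass(a * D, cond, N * pitch) / m_0
  }

  if (ratio_at(1L) < scenario$threshold) return(0L)
  # blockwise ascending scan; m_ratio is monotone decreasing in N
  lo <- 1L
  block <- 1024L
  while (lo <= N_max) {
    hi <- min(lo + block - 1L, N_max)
    N <- lo:hi
    ok <- ratio_at(N) >= scenario$threshold
    if (!all(ok)) return(N[which.min(ok)] - 1L)
    lo <- hi + 1L
    block <- block * 2L
  }
  stop(sprintf("penetration limit exceeds N_max = %d; raise N_max", N_max),
       call. = FALSE)
}

#' Forward prediction for a filter-stack barrier
#'
#' Chains the full model for a membrane experiment: stack geometry gives
#' (L, Y); the retention law gives `a` and `D_ef = a*D`; the quasi-steady
#' closed form gives the permeated mass, acceptor concentration and flux.
#'
#' @param stack A [filter_stack()].
#' @param particle A [particle_spec()].
#' @param medium A [medium_spec()].
#' @param cond A [cell_conditions()].
#' @param k Adsorption model constant, non-negative.
#'
#' @return An object of class `transport_result`: list with `D`, `D_ef`,
#'   `a`, `Y`, `L`, `J` (g/(m^2*s)), `c_p` (g/m^3), `m_p` (g) and `m_ratio`.
#' @examples
#' res <- membrane_prediction(build_stack("F118"),
#'                            particle_spec("nanoAg", 9e-9, 7874),
#'                            medium_spec(),
#'                            cell_conditions(3.14e-4, 1e-5, 43200, 400),
#'                            k = 0.3884)
#' res$a
#' @export
membrane_prediction <- function(stack, particle, medium, cond, k) {
  stopifnot(inherits(stack, "filter_stack"))
  if (k < 0) stop("'k' must be non-negative", call. = FALSE)
  p <- stack_properties(stack)
  D <- diffusion_coefficient(particle, medium)
  a <- retention_fraction(p$Y, k)
  D_ef <- a * D
  m_p <- permeated_mass(D_ef, cond, p$L)
  structure(list(D = D, D_ef = D_ef, a = a, Y = p$Y, L = p$L,
                 J = mass_flux(m_p, cond$A, cond$t),
                 c_p = m_p / cond$V, m_p = m_p,
                 m_ratio = m_p / (cond$c0 * cond$V)),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat("<transport_result>\n")
  cat(sprintf("  barrier: L = %g um, Y = %.3f, a = %.4f\n",
              x$L * 1e6, x$Y, x$a))
  cat(sprintf("  D = %.4g m^2/s, D_ef = %.4g m^2/s\n", x$D, x$D_ef))
  cat(sprintf("  c_p = %.4g mg/L, m_p = %.4g g (m_p/m_0 = %.4g)\n",
              x$c_p, x$m_p, x$m_ratio))
  invisible(x)
}
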