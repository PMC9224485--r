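# Surface-parameter (Y) geometry for woven mesh filters, filter stacks and
# the brick-and-mortar stratum corneum. Y is the dimensionless ratio of the
# solid surface area available for particle deposition (thread mantles or
# brick faces) to the reference barrier cross-section A_F. It is invariant
# to the choice of A_F; the default reference region is a 1 cm^2 square.

#' Woven mesh filter specification
#'
#' A single woven filter layer: mesh size, thread diameter, wettability and
#' single-layer thickness, all in SI units.
#'
#' @param label Short identifier, e.g. `"F118"`.
#' @param wettability `"HI"` (hydrophilic) or `"HF"` (hydrophobic).
#' @param l_h Mesh size (open width between threads) in metres.
#' @param d_f Thread diameter in metres.
#' @param thickness Single-layer thickness in metres.
#'
#' @return An object of class `mesh_filter`.
#' @examples
#' f118 <- mesh_filter("F118", "HI", l_h = 118e-6, d_f = 55.46e-6,
#'                     thickness = 55.5e-6)
#' @export
mesh_filter <- function(label, wettability = c("HI", "HF"), l_h, d_f, thickness) {
  stopifnot(is.character(label), length(label) == 1L)
  wettability <- match.arg(wettability)
  .check_positive(l_h, "l_h")
  .check_positive(d_f, "d_f")
  .check_positive(thickness, "thickness")
  structure(list(label = label, wettability = wettability,
                 l_h = l_h, d_f = d_f, thickness = thickness),
            class = "mesh_filter")
}

#' @export
print.mesh_filter <- function(x, ...) {
  cat(sprintf("<mesh_filter> %s (%s): mesh %g um, thread %g um, thickness %g um\n",
              x$label, x$wettability, x$l_h * 1e6, x$d_f * 1e6,
              x$thickness * 1e6))
  invisible(x)
}

#' Ordered stack of mesh filters
#'
#' @param ... `mesh_filter` objects, or a single list of them, ordered from
#'   the donor side down.
#'
#' @return An object of class `filter_stack`.
#' @export
filter_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]]) &&
      !inherits(layers[[1L]], "mesh_filter")) {
    layers <- layers[[1L]]
  }
  if (length(layers) == 0L) stop("a filter stack needs at least one layer",
                                 call. = FALSE)
  ok <- vapply(layers, inherits, logical(1), "mesh_filter")
  if (!all(ok)) stop("all stack layers must be mesh_filter objects",
                     call. = FALSE)
  structure(list(layers = layers), class = "filter_stack")
}

#' @export
print.filter_stack <- function(x, ...) {
  labs <- vapply(x$layers, `[[`, character(1), "label")
  p <- stack_properties(x)
  cat(sprintf("<filter_stack> %s: L = %g um, Y = %.3f\n",
              paste(labs, collapse = " + "), p$L * 1e6, p$Y))
  invisible(x)
}

#' Thread counts of a woven mesh over a reference side length
#'
#' Counts the threads crossing a square region of side `h`. In the plain
#' direction threads repeat every `d_f + l_h`, giving `n_x = h/(d_f + l_h)`.
#' In the other direction the weave places a double thread in every other
#' splice, so three threads span `3*d_f + 2*l_h` and
#' `n_y = 3*h/(3*d_f + 2*l_h)`.
#'
#' Counts are real-valued by default, and those are what the surface
#' parameter uses. With `rounded = TRUE` the function instead counts the
#' whole threads that physically fit in the length: threads whose full
#' diameter lies within `h`, walking the weave pattern from one edge.
#'
#' @param filter A [mesh_filter()].
#' @param h Reference side length in metres (default 1 cm).
#' @param rounded If `TRUE`, count whole threads fitting in `h` instead of
#'   returning real-valued densities.
#'
#' @return Named list with `n_x` and `n_y`.
#' @examples
#' f118 <- mesh_filter("F118", "HI", 118e-6, 55.46e-6, 55.5e-6)
#' thread_counts(f118)                  # 57.65, 74.56
#' thread_counts(f118, rounded = TRUE)  # 58, 74
#' @export
thread_counts <- function(filter, h = 0.01, rounded = FALSE) {
  stopifnot(inherits(filter, "mesh_filter"))
  .check_positive(h, "h")
  d_f <- filter$d_f
  l_h <- filter$l_h
  if (!rounded) {
    return(list(n_x = h / (d_f + l_h), n_y = 3 * h / (3 * d_f + 2 * l_h)))
  }
  # whole threads whose diameter fits within h
  n_x <- if (h < d_f) 0 else floor((h - d_f) / (d_f + l_h)) + 1
  # double-splice direction: triplets spanning hc = 3 d_f + 2 l_h, thread
  # starts at offsets {0, d_f + l_h, 2 d_f + 2 l_h} within each triplet
  hc <- 3 * d_f + 2 * l_h
  full <- floor(h / hc)
  rest <- h - full * hc
  offs <- c(0, d_f + l_h, 2 * d_f + 2 * l_h)
  n_y <- 3 * full + sum(offs + d_f <= rest)
  list(n_x = n_x, n_y = n_y)
}

#' Surface parameter Y of a single woven filter
#'
#' Treats each thread as a full cylinder of length `h` crossing the square
#' reference region of area `A_F = h^2`:
#' `Y = (n_x + n_y) * pi * d_f * h / A_F`, with unrounded thread counts.
#'
#' @inheritParams thread_counts
#' @param A_F Reference area in m^2 (square region; default 1 cm^2). Y is
#'   invariant to this choice.
#'
#' @return Dimensionless surface parameter.
#' @export
mesh_surface_parameter <- function(filter, A_F = 1e-4) {
  stopifnot(inherits(filter, "mesh_filter"))
  .check_positive(A_F, "A_F")
  h <- sqrt(A_F)
  n <- thread_counts(filter, h = h)
  (n$n_x + n$n_y) * pi * filter$d_f * h / A_F
}

#' Total thickness and surface parameter of a filter stack
#'
#' Both quantities are additive over layers: `L` is the sum of layer
#' thicknesses and `Y` the sum of per-layer surface parameters.
#'
#' @param stack A [filter_stack()].
#' @param A_F Reference area in m^2.
#'
#' @return Named list with `L` (metres) and `Y` (dimensionless).
#' @export
stack_properties <- function(stack, A_F = 1e-4) {
  stopifnot(inherits(stack, "filter_stack"))
  L <- sum(vapply(stack$layers, `[[`, numeric(1), "thickness"))
  Y <- sum(vapply(stack$layers, mesh_surface_parameter, numeric(1), A_F = A_F))
  list(L = L, Y = Y)
}

#' Brick-and-mortar stratum corneum geometry
#'
#' Square corneocyte "bricks" of side `w` and depth `x_k`, separated by
#' intercellular cement of thickness `x_c` (the same value laterally and
#' between layers). The layer pitch is `x_k + x_c`.
#'
#' @param w Brick side length in metres.
#' @param x_k Brick thickness (depth dimension) in metres.
#' @param x_c Cement gap thickness in metres.
#'
#' @return An object of class `brick_geometry`.
#' @examples
#' brick_geometry()  # 35 x 35 x 1 um bricks, 0.05 um cement
#' @export
brick_geometry <- function(w = 35e-6, x_k = 1e-6, x_c = 0.05e-6) {
  .check_positive(w, "w")
  .check_positive(x_k, "x_k")
  .check_positive(x_c, "x_c")
  structure(list(w = w, x_k = x_k, x_c = x_c), class = "brick_geometry")
}

#' @export
print.brick_geometry <- function(x, ...) {
  cat(sprintf("<brick_geometry> %g x %g x %g um bricks, %g um cement (pitch %g um)\n",
              x$w * 1e6, x$w * 1e6, x$x_k * 1e6, x$x_c * 1e6,
              (x$x_k + x$x_c) * 1e6))
  invisible(x)
}

#' Total surface area of one brick
#'
#' Sum of the areas of all six faces of a `w x w x x_k` cuboid:
#' `A_S = 2*w^2 + 4*w*x_k`.
#'
#' @param g A [brick_geometry()].
#'
#' @return Area in m^2.
#' @export
brick_total_area <- function(g) {
  stopifnot(inherits(g, "brick_geometry"))
  2 * g$w^2 + 4 * g$w * g$x_k
}

#' Number of bricks in one layer over a reference area
#'
#' Bricks tile a square of side `h = sqrt(A_F)` with pitch `w + x_c`, so the
#' (real-valued) linear count is `n_d = h/(w + x_c)` and `n = n_d^2`.
#'
#' @inheritParams brick_total_area
#' @param A_F Reference area in m^2 (square region).
#'
#' @return Real-valued brick count.
#' @export
bricks_per_layer <- function(g, A_F = 1e-4) {
  stopifnot(inherits(g, "brick_geometry"))
  .check_positive(A_F, "A_F")
  (sqrt(A_F) / (g$w + g$x_c))^2
}

#' Surface parameter Y of a single brick layer
#'
#' `Y = n * A_S / A_F` with the unrounded brick count; additive over layers,
#' so an `N`-layer wall has `N * Y_layer`.
#'
#' @inheritParams bricks_per_layer
#'
#' @return Dimensionless surface parameter per layer.
#' @examples
#' brick_layer_surface_parameter(brick_geometry())  # 2.108
#' @export
brick_layer_surface_parameter <- function(g, A_F = 1e-4) {
  bricks_per_layer(g, A_F) * brick_total_area(g) / A_F
}
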