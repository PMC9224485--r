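# Modified Langmuir retention law and estimation of its single constant k.
#
# The law maps the surface parameter Y of a barrier to the fraction a of
# diffusive transport that survives adsorption:
#
#   a(Y; k) = 1 - k*Y/(1 + k*Y) = 1/(1 + k*Y)
#
# It is the Langmuir isotherm with the monolayer capacity fixed at 1 and the
# adsorbate "pressure" replaced by the deposition surface area, read as the
# escaping rather than the adsorbed fraction.

#' Retained (transmitted) fraction under the modified Langmuir law
#'
#' `a = 1/(1 + k*Y)`, in (0, 1]; equals 1 when either argument is 0 (no
#' surface or no adsorption affinity) and decreases strictly in both.
#'
#' @param Y Surface parameter, dimensionless, non-negative.
#' @param k Model constant, dimensionless per unit Y, non-negative.
#'
#' @return Retardation coefficient `a` in (0, 1].
#' @examples
#' retention_fraction(Y = 2.30, k = 0.3884)
#' @export
retention_fraction <- function(Y, k) {
  if (any(Y < 0)) stop("'Y' must be non-negative", call. = FALSE)
  if (any(k < 0)) stop("'k' must be non-negative", call. = FALSE)
  1 / (1 + k * Y)
}

#' Surface parameter implied by a retardation coefficient
#'
#' Algebraic inverse of [retention_fraction()]: `Y = (1/a - 1)/k`.
#'
#' @param a Retardation coefficient in (0, 1].
#' @param k Model constant, strictly positive.
#'
#' @return Surface parameter Y.
#' @export
invert_retention <- function(a, k) {
  if (any(a <= 0 | a > 1)) stop("'a' must lie in (0, 1]", call. = FALSE)
  .check_positive(k, "k")
  (1 / a - 1) / k
}

#' Model constant from a single (a, Y) observation
#'
#' `k = (1/a - 1)/Y`. A single barrier measurement identifies k exactly under
#' the model; pooled fits over several barriers ([fit_model_constant()]) are
#' preferred because single-point estimates scatter.
#'
#' @param a Retardation coefficient in (0, 1].
#' @param Y Surface parameter, strictly positive (unless `a = 1`).
#'
#' @return Model constant k.
#' @export
model_constant_from_single <- function(a, Y) {
  if (any(a <= 0 | a > 1)) stop("'a' must lie in (0, 1]", call. = FALSE)
  if (any(Y < 0)) stop("'Y' must be non-negative", call. = FALSE)
  if (any(Y == 0 & a < 1)) {
    stop("inconsistent observation: a < 1 with no surface (Y = 0)",
         call. = FALSE)
  }
  out <- ifelse(a == 1, 0, (1 / a - 1) / Y)
  as.numeric(out)
}

#' Fit the model constant k by nonlinear least squares
#'
#' Minimises the unweighted residual sum of squares
#' `sum((a_obs - 1/(1 + k*Y_obs))^2)` over `k >= 0` by damped 1-D
#' Gauss-Newton. Initialised at the median of the single-point estimates;
#' converged when the relative change in k drops below `tol` (default 1e-10)
#' or after `max_iter` iterations. The objective is unimodal in k for
#' observations with `a` in (0, 1], so no multistart is needed.
#'
#' Observations with `a > 1` (possible in noisy synthetic data) are retained
#' but counted in the `n_flagged` field; they pull the estimate toward 0.
#'
#' @param observations A data frame with numeric columns `Y` and `a`
#'   (other columns are ignored), or a numeric vector of Y values.
#' @param a Retardation coefficients, if `observations` is a vector.
#' @param weights Optional non-negative per-observation weights; default
#'   unweighted.
#' @param tol Relative convergence tolerance on k.
#' @param max_iter Maximum Gauss-Newton iterations.
#'
#' @return An object of class `adsorption_fit`: list with `k`, `rss`,
#'   `n_obs`, `residuals` (a_obs - a_pred), `n_flagged`, `iterations`,
#'   `converged`, and `note` (non-`NA` for degenerate inputs).
#' @examples
#' obs <- retention_observations()
#' fit_model_constant(obs[obs$group == "HI", ])
#' @export
fit_model_constant <- function(observations, a = NULL, weights = NULL,
                               tol = 1e-10, max_iter = 200L) {
  if (is.data.frame(observations)) {
    Y <- observations$Y
    a <- observations$a
  } else {
    Y <- observations
  }
  if (is.null(Y) || is.null(a) || length(Y) != length(a)) {
    stop("need matching Y and a observations", call. = FALSE)
  }
  if (length(Y) == 0L) stop("no observations to fit", call. = FALSE)
  if (any(Y < 0) || any(a <= 0)) {
    stop("observations must have Y >= 0 and a > 0", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(Y))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)

  n_flagged <- sum(a > 1)
  rss_at <- function(k) sum(weights * (a - 1 / (1 + k * Y))^2)

  note <- NA_character_
  if (all(a >= 1)) {
    # no measurable adsorption anywhere: the best non-negative k is 0
    k <- 0
    iterations <- 0L
    converged <- TRUE
    note <- "all observations have a >= 1; returning k = 0"
  } else {
    k0 <- stats::median(pmax(0, (1 / a - 1) / pmax(Y, .Machine$double.eps)))
    k <- max(k0, 0)
    converged <- FALSE
    iterations <- 0L
    for (it in seq_len(max_iter)) {
      iterations <- it
      pred <- 1 / (1 + k * Y)
      r <- a - pred
      J <- -Y * pred^2             # d pred / d k
      denom <- sum(weights * J^2)
      if (denom == 0) break
      step <- sum(weights * J * r) / denom
      # damp the step until the objective does not increase
      rss_old <- sum(weights * r^2)
      lambda <- 1
      k_new <- max(0, k + step)
      while (rss_at(k_new) > rss_old && lambda > 1e-12) {
        lambda <- lambda / 2
        k_new <- max(0, k + lambda * step)
      }
      rel <- abs(k_new - k) / max(abs(k), .Machine$double.eps)
      k <- k_new
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }

  residuals <- a - 1 / (1 + k * Y)
  structure(list(k = k, rss = sum(weights * residuals^2),
                 n_obs = length(Y), residuals = residuals,
                 n_flagged = n_flagged, iterations = iterations,
                 converged = converged, note = note),
            class = "adsorption_fit")
}

#' @export
print.adsorption_fit <- function(x, ...) {
  cat(sprintf("<adsorption_fit> k = %.6g  (rss = %.4g over %d observations)\n",
              x$k, x$rss, x$n_obs))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  if (x$n_flagged > 0) cat(sprintf("flagged: %d observations with a > 1\n",
                                   x$n_flagged))
  invisible(x)
}

#' Write a fit result as a small JSON document
#'
#' Emits `{k, rss, n_obs}` for downstream consumption.
#'
#' @param fit An `adsorption_fit`.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "adsorption_fit"))
  jsonlite::write_json(list(k = fit$k, rss = fit$rss, n_obs = fit$n_obs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
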