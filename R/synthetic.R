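# Synthetic Franz-cell experiments: the forward model generates true acceptor
# concentrations per filter stack, multiplicative Gaussian noise emulates the
# conductometric measurement error, and the inversion chain (c_p -> D_ef ->
# a) recovers the quantities the analysis works with. Used for
# parameter-recovery studies of the adsorption constant k.

#' Configuration for a synthetic membrane experiment
#'
#' The default design mirrors the membrane study protocol: the twelve filter
#' configurations, four replicate measurements per configuration (two
#' chambers x two runs), 12 h at 400 mg/L, with multiplicative Gaussian
#' noise of 5% relative standard deviation on the acceptor concentration.
#'
#' @param true_k Generating adsorption constant, non-negative.
#' @param stacks Named list of [filter_stack()] objects (names are the stack
#'   labels in the output).
#' @param particle A [particle_spec()].
#' @param medium A [medium_spec()].
#' @param conditions A [cell_conditions()].
#' @param noise_rel_sd Relative standard deviation of the multiplicative
#'   Gaussian noise on c_p, non-negative.
#' @param replicates Measurements per stack, at least 1.
#' @param seed Root seed; per-stack/per-replicate substreams are derived
#'   deterministically from it, so the same seed reproduces the same table
#'   bit for bit and extending `replicates` leaves earlier draws unchanged.
#'
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(true_k = 0.3884, replicates = 2, seed = 1)
#' head(simulate_measurements(cfg))
#' @export
synthetic_config <- function(true_k = 0.3884,
                             stacks = default_stack_set(),
                             particle = particle_spec("nanoAg", 9e-9, 7874),
                             medium = medium_spec(),
                             conditions = cell_conditions(A = 3.14e-4,
                                                          V = 1e-5,
                                                          t = 43200,
                                                          c0 = 400),
                             noise_rel_sd = 0.05,
                             replicates = 4L,
                             seed = 1L) {
  if (true_k < 0) stop("'true_k' must be non-negative", call. = FALSE)
  if (noise_rel_sd < 0) stop("'noise_rel_sd' must be non-negative",
                             call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("'replicates' must be at least 1", call. = FALSE)
  if (is.null(names(stacks)) || any(!nzchar(names(stacks)))) {
    stop("'stacks' must be a named list", call. = FALSE)
  }
  ok <- vapply(stacks, inherits, logical(1), "filter_stack")
  if (!all(ok)) stop("'stacks' must contain filter_stack objects",
                     call. = FALSE)
  structure(list(true_k = true_k, stacks = stacks, particle = particle,
                 medium = medium, conditions = conditions,
                 noise_rel_sd = noise_rel_sd, replicates = replicates,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' The twelve filter configurations of the membrane study
#'
#' @param library Filter library data frame, as from [filter_library()].
#'
#' @return Named list of [filter_stack()] objects.
#' @export
default_stack_set <- function(library = filter_library()) {
  designations <- c("F118", "F63", "F1", "F118+F63", "F118+F63+F1",
                    "F1+F1", "F1+F1+F1", "F9*", "F9*+F9*", "F9*+F9*+F9*",
                    "F1+F9*+F1", "F9*+F1+F9*")
  stats::setNames(lapply(designations, build_stack, library = library),
                  designations)
}

# deterministic substream seed for (dataset, stack, replicate); kept below
# 2^31 so it is a valid R integer
.substream_seed <- function(root, stack_idx, replicate) {
  as.integer((as.double(root) * 48271 + stack_idx * 10007 + replicate * 101) %%
               2147483629)
}

#' Simulate noisy Franz-cell measurements
#'
#' For each stack and replicate, the true acceptor concentration comes from
#' the forward model at `true_k`; the observation is
#' `c_p_observed = c_p_true * (1 + e)` with `e ~ N(0, noise_rel_sd)`.
#' Negative draws are truncated to 0 and flagged. Derived quantities
#' (effective diffusivity and retardation) are recomputed from the observed
#' concentration through the inversion chain, exactly as an analyst would.
#'
#' @param config A [synthetic_config()].
#' @param dataset Integer tag entering the substream derivation, so that
#'   replicated datasets (e.g. in [parameter_recovery_study()]) draw
#'   independent noise from one root seed.
#'
#' @return A data frame with one row per (stack, replicate): `stack`,
#'   `replicate`, `Y`, `L`, `c_p_true`, `c_p_observed`, `truncated`,
#'   `D_ef`, `a`.
#' @export
simulate_measurements <- function(config, dataset = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  D <- diffusion_coefficient(config$particle, config$medium)
  root <- config$seed + (dataset - 1L) * 7919L
  reps <- seq_len(config$replicates)
  per_stack <- lapply(seq_along(config$stacks), function(s) {
    pred <- membrane_prediction(config$stacks[[s]], config$particle,
                                config$medium, config$conditions,
                                config$true_k)
    eps <- vapply(reps, function(r) {
      set.seed(.substream_seed(root, s, r))
      stats::rnorm(1L, mean = 0, sd = config$noise_rel_sd)
    }, numeric(1))
    c_obs <- pred$c_p * (1 + eps)
    truncated <- c_obs < 0
    c_obs[truncated] <- 0
    D_ef <- effective_diffusivity(c_obs, config$conditions, pred$L)
    data.frame(stack = names(config$stacks)[s], replicate = reps,
               Y = pred$Y, L = pred$L, c_p_true = pred$c_p,
               c_p_observed = c_obs, truncated = truncated, D_ef = D_ef,
               a = suppressWarnings(retardation_coefficient(D_ef, D)))
  })
  out <- do.call(rbind, per_stack)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery study for the adsorption constant
#'
#' Simulates `n_datasets` independent synthetic experiments from one
#' configuration, fits k on each via [fit_model_constant()] applied to the
#' derived (Y, a) observations, and summarises the estimates. Requires at
#' least two distinct stack Y values, since a single Y cannot identify k in
#' the presence of unknown noise.
#'
#' @param config A [synthetic_config()].
#' @param n_datasets Number of independent simulated datasets.
#'
#' @return An object of class `recovery_summary`: list with `k_true`,
#'   `k_hat` (vector), `median`, `bias` (median - true), `sd`, `n_datasets`.
#' @examples
#' cfg <- synthetic_config(noise_rel_sd = 0, replicates = 1, seed = 1)
#' parameter_recovery_study(cfg, n_datasets = 1)$bias  # 0 without noise
#' @export
parameter_recovery_study <- function(config, n_datasets = 100L) {
  stopifnot(inherits(config, "synthetic_config"))
  Ys <- vapply(config$stacks, function(s) stack_properties(s)$Y, numeric(1))
  if (length(unique(signif(Ys, 12))) < 2L) {
    stop("k is not identifiable: need at least two distinct stack Y values",
         call. = FALSE)
  }
  n_datasets <- as.integer(n_datasets)
  k_hat <- vapply(seq_len(n_datasets), function(ds) {
    m <- simulate_measurements(config, dataset = ds)
    m <- m[m$a > 0, , drop = FALSE] # zero-truncated draws carry no a information
    fit_model_constant(m[, c("Y", "a")])$k
  }, numeric(1))
  structure(list(k_true = config$true_k, k_hat = k_hat,
                 median = stats::median(k_hat),
                 bias = stats::median(k_hat) - config$true_k,
                 sd = stats::sd(k_hat), n_datasets = n_datasets),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf(
    "<recovery_summary> true k = %g; median k_hat = %.5g (bias %.3g, sd %.3g) over %d datasets\n",
    x$k_true, x$median, x$bias, x$sd, x$n_datasets))
  invisible(x)
}

#' Write a recovery summary as JSON
#'
#' @param summary A `recovery_summary`.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_recovery_summary <- function(summary, path) {
  stopifnot(inherits(summary, "recovery_summary"))
  jsonlite::write_json(summary[c("k_true", "median", "bias", "sd",
                                 "n_datasets")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
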