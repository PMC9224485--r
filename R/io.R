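# File-facing interfaces: flat scenario config files with explicit units in
# the key names, and profile export as CSV.

.scenario_keys <- c(
  "particle_name", "diameter_nm", "solid_density_kg_m3",
  "temperature_k", "viscosity_pa_s", "fluid_density_kg_m3",
  "area_cm2", "volume_cm3", "c0_mg_per_l", "time_h",
  "cell_side_um", "cell_thickness_um", "cement_um",
  "k", "threshold")

.scenario_required <- setdiff(.scenario_keys, c("particle_name", "threshold"))

#' Read a skin scenario from a flat config file
#'
#' The file is a flat YAML mapping whose keys carry their units, e.g.
#' `diameter_nm: 9`, `viscosity_pa_s: 0.001`, `c0_mg_per_l: 10000`,
#' `time_h: 12`, `cell_side_um: 35`. The schema is strict: unknown keys are
#' rejected and all keys except `particle_name` (default `"particle"`) and
#' `threshold` (default 0.005) are required. Values are converted to SI
#' internally.
#'
#' @param path Path to the config file.
#'
#' @return A [skin_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("scenario config must be a flat key-value mapping",
                          call. = FALSE)
  unknown <- setdiff(names(cfg), .scenario_keys)
  if (length(unknown) > 0L) {
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(.scenario_required, names(cfg))
  if (length(missing) > 0L) {
    stop("missing scenario keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L) {
      stop(sprintf("scenario key '%s' must be a single number", key),
           call. = FALSE)
    }
    v
  }
  skin_scenario(
    geometry = brick_geometry(w = num("cell_side_um") * 1e-6,
                              x_k = num("cell_thickness_um") * 1e-6,
                              x_c = num("cement_um") * 1e-6),
    particle = particle_spec(
      if (is.null(cfg$particle_name)) "particle" else cfg$particle_name,
      d = num("diameter_nm") * 1e-9,
      rho_s = num("solid_density_kg_m3")),
    medium = medium_spec(T = num("temperature_k"),
                         mu = num("viscosity_pa_s"),
                         rho_c = num("fluid_density_kg_m3")),
    conditions = cell_conditions(A = num("area_cm2") * 1e-4,
                                 V = num("volume_cm3") * 1e-6,
                                 t = num("time_h") * 3600,
                                 c0 = num("c0_mg_per_l")),
    k = num("k"),
    threshold = if (is.null(cfg$threshold)) 0.005 else num("threshold"))
}

#' Write a penetration profile as CSV
#'
#' Columns `N,L_um,Y,a,D_ef_m2_s,m_p_g,m_ratio`; floats are emitted with six
#' significant digits.
#'
#' @param profile A `penetration_profile` from [permeation_profile()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "penetration_profile"))
  out <- data.frame(N = profile$N,
                    L_um = signif(profile$L * 1e6, 6),
                    Y = signif(profile$Y, 6),
                    a = signif(profile$a, 6),
                    D_ef_m2_s = signif(profile$D_ef, 6),
                    m_p_g = signif(profile$m_p, 6),
                    m_ratio = signif(profile$m_ratio, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
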