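# Packaged reference data: the four commercial woven polyacrylamide filters
# (mesh size, thread diameter, single-layer thickness, wettability) and the
# 24 Franz-cell retention observations (12 filter configurations x nanoAg /
# nanoCu) from the membrane diffusion study.

#' Packaged woven-filter library
#'
#' The four commercial filter types used in the membrane diffusion study,
#' read from a delimited table with columns `label`, `wettability`,
#' `mesh_size_um`, `thread_diameter_um`, `thickness_um`.
#'
#' @param path Optional path to an alternative filter library CSV in the same
#'   format; defaults to the packaged table.
#'
#' @return A data frame, one row per filter type.
#' @examples
#' filter_library()
#' @export
filter_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "filters.csv", package = "dermadiff",
                        mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a mesh_filter from a filter-library row
#'
#' @param label Filter label present in the library.
#' @param library A filter library data frame, as from [filter_library()].
#'
#' @return A [mesh_filter()] in SI units.
#' @export
library_filter <- function(label, library = filter_library()) {
  row <- library[library$label == label, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("filter '%s' not found in library", label), call. = FALSE)
  }
  mesh_filter(row$label, row$wettability,
              l_h = row$mesh_size_um * 1e-6,
              d_f = row$thread_diameter_um * 1e-6,
              thickness = row$thickness_um * 1e-6)
}

#' Build a filter stack from a "F118+F63" style designation
#'
#' Layer labels are separated by `+`; each must exist in the library.
#'
#' @param designation Character like `"F118+F63+F1"` (or a character vector
#'   of labels).
#' @inheritParams library_filter
#'
#' @return A [filter_stack()].
#' @examples
#' build_stack("F118+F63")
#' @export
build_stack <- function(designation, library = filter_library()) {
  labels <- if (length(designation) == 1L) {
    trimws(strsplit(designation, "+", fixed = TRUE)[[1L]])
  } else {
    designation
  }
  filter_stack(lapply(labels, library_filter, library = library))
}

#' Packaged Franz-cell retention observations
#'
#' The 24 (surface parameter Y, retardation a) observations from the
#' membrane study: 12 filter configurations, each measured with silver
#' (9 nm) and copper (12 nm) nanoparticles. The `group` column separates
#' hydrophilic (`HI`) and hydrophobic (`HF`) configurations; the two stacks
#' interleaving both wettabilities are marked `mixed` and belong to neither
#' fit set.
#'
#' @param group Optional filter: `"HI"`, `"HF"` or `"mixed"`.
#'
#' @return A data frame with columns `config`, `L_um`, `Y`, `group`,
#'   `particle`, `D_ef_m2_s`, `a`.
#' @examples
#' head(retention_observations("HI"))
#' @export
retention_observations <- function(group = NULL) {
  path <- system.file("extdata", "retention_observations.csv",
                      package = "dermadiff", mustWork = TRUE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(group)) {
    group <- match.arg(group, c("HI", "HF", "mixed"))
    obs <- obs[obs$group == group, , drop = FALSE]
  }
  obs
}
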