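#' Total potential energy of a configuration
#'
#' Sums the backbone FENE springs, stacking wells, native-only hydrogen
#' bonds, site-site excluded volume, and crowder-site / crowder-crowder
#' excluded volume, all under minimum-image periodic boundary conditions.
#' Energies are in units of \eqn{k_B T_0} (\eqn{T_0} = 300 K).
#'
#' A FENE bond stretched beyond its maximum extension is an overstretch: the
#' energy is not silently clamped, an error of class `crowdna_overstretch`
#' is raised instead (unless `terms = TRUE`, which returns the term table
#' with the `overstretch` flag for inspection).
#'
#' @param conf a `cg_configuration`.
#' @param topo a `cg_topology`.
#' @param params interaction parameters.
#' @param terms if `TRUE` return a one-row tibble with the per-term
#'   decomposition instead of the scalar total.
#' @return scalar energy, or a tibble with columns `total`, `fene`,
#'   `stacking`, `hbond`, `excluded`, `crowder`, `overstretch`.
#' @examples
#' fx <- build_fixture("duplex8", "bound")
#' total_energy(fx$configuration, fx$topology)
#' @export
total_energy <- function(conf, topo, params = interaction_params(),
                         terms = FALSE) {
  e <- cpp_energy(sys_list(conf, topo), params)
  if (terms) return(as_tibble(e))
  if (isTRUE(e$overstretch))
    abort("FENE backbone bond stretched beyond its maximum extension",
          class = "crowdna_overstretch")
  e$total
}

#' Hydrogen-bond energies of the native pairs
#'
#' @inheritParams total_energy
#' @return tibble with columns `pair` (row in `topo$native_pairs`), `i`,
#'   `j` (0-based nucleotide indices), `energy` and `formed` (energy below
#'   `-bp_frac * eps_hb`).
#' @export
hb_energies <- function(conf, topo, params = interaction_params()) {
  e <- cpp_hb_pair_energies(sys_list(conf, topo), params)
  tibble(pair = seq_along(e), i = topo$native_pairs[, 1],
         j = topo$native_pairs[, 2], energy = e,
         formed = e < -params$bp_frac * params$eps_hb)
}

#' Count formed native base pairs
#'
#' A native pair counts as formed when its hydrogen-bond energy is below
#' `-bp_frac * eps_hb` (default fraction 0.1), the standard well-occupancy
#' criterion for bond definitions.
#'
#' @inheritParams total_energy
#' @return integer in `[0, n_native_pairs]`.
#' @export
count_native_bp <- function(conf, topo, params = interaction_params()) {
  cpp_count_bp(sys_list(conf, topo), params)
}

#' Minimum distance over native pairs
#'
#' Minimum-image distance (nm) between the base interaction sites of native
#' pairs, minimised over a pair subset (e.g. toehold pairs only).
#'
#' @inheritParams total_energy
#' @param subset integer vector of 1-based rows of `topo$native_pairs`, or a
#'   subset name from `topo$subsets`; `NULL` means all native pairs.
#' @return minimum distance in nm.
#' @export
min_native_distance <- function(conf, topo, subset = NULL,
                                params = interaction_params()) {
  rows <- resolve_subset(topo, subset)
  if (length(rows) == 0) abort("pair subset must be non-empty")
  cpp_min_dist(sys_list(conf, topo), params, as.integer(rows - 1L))
}

# internal: turn a subset spec (NULL / name / 1-based rows) into 1-based rows
resolve_subset <- function(topo, subset) {
  if (is.null(subset)) return(seq_len(nrow(topo$native_pairs)))
  if (is.character(subset)) {
    if (is.null(topo$subsets) || is.null(topo$subsets[[subset]]))
      abort(paste0("unknown pair subset '", subset, "'"))
    return(topo$subsets[[subset]])
  }
  rows <- as.integer(subset)
  if (any(rows < 1) || any(rows > nrow(topo$native_pairs)))
    abort("pair subset rows out of range")
  rows
}
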