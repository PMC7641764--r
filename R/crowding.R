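# Crowder specification, packing at a target excluded volume fraction, and
# the crowder pair potential.

#' Crowder specification
#'
#' Records the crowder radius, target excluded volume fraction, and the
#' reference constants used by the dynamics scaling rules: crowders keep the
#' mass density of the smallest (reference) sphere, and their diffusion
#' coefficient scales inversely with radius.
#'
#' @param r_c crowder radius (nm).
#' @param phi excluded volume fraction, in `[0, 0.55)` (requests above
#'   random-close-packing feasibility are refused).
#' @param m_0 reference mass (one DNA nucleotide).
#' @param r_0 reference radius (nm), the smallest crowder studied.
#' @param D_0 reference diffusion coefficient (nm^2/ps), one DNA nucleotide.
#' @return an object of class `crowder_spec`.
#' @export
crowder_spec <- function(r_c = 0.85, phi = 0, m_0 = 1, r_0 = 0.85,
                         D_0 = 0.24) {
  if (r_c <= 0) abort("crowder radius must be positive")
  if (phi < 0 || phi >= 0.55) abort("phi must lie in [0, 0.55)")
  if (m_0 <= 0 || r_0 <= 0 || D_0 <= 0) abort("reference constants must be positive")
  structure(list(r_c = r_c, phi = phi, m_0 = m_0, r_0 = r_0, D_0 = D_0),
            class = "crowder_spec")
}

#' Number of crowders realising a target volume fraction
#'
#' The excluded volume fraction of `N` spheres of radius `r_c` in a cubic box
#' of edge `L_box` is `N (4/3) pi r_c^3 / L_box^3`; this returns the nearest
#' integer count together with the volume fraction it actually achieves.
#'
#' @param phi target excluded volume fraction in `[0, 0.55)`.
#' @param r_c crowder radius (nm).
#' @param L_box box edge (nm); must exceed one crowder diameter.
#' @return tibble with columns `count`, `phi_target`, `phi_achieved`.
#' @examples
#' crowders_for_phi(0.1, 0.85, 20)
#' @export
crowders_for_phi <- function(phi, r_c, L_box) {
  if (any(phi < 0) || any(phi >= 0.55))
    abort("phi must lie in [0, 0.55): denser packings are infeasible")
  if (r_c <= 0) abort("crowder radius must be positive")
  if (L_box <= 2 * r_c)
    abort("infeasible packing: box must exceed one crowder diameter",
          class = "crowdna_packing_error")
  vc <- 4 / 3 * pi * r_c^3
  count <- as.integer(round(phi * L_box^3 / vc))
  tibble(count = count, phi_target = phi,
         phi_achieved = count * vc / L_box^3)
}

#' Pack crowders at random without overlaps
#'
#' Random sequential addition with a Monte Carlo relaxation fallback. All
#' pairwise minimum-image centre distances are at least `2 r_c (1 - delta)`,
#' and crowders keep a clearance of `r_c + r_site` from any supplied DNA
#' interaction site. Deterministic for a given seed.
#'
#' @param count number of crowders.
#' @param r_c crowder radius (nm).
#' @param L_box box edge (nm).
#' @param seed RNG seed (recorded in output metadata).
#' @param existing_sites optional k x 3 matrix of DNA site positions to keep
#'   clear of.
#' @param clearance centre-to-site clearance (nm); default `r_c + r_site`
#'   with `r_site` from `params`.
#' @param delta packing slack avoiding floating-point contact violations.
#' @param params interaction parameters (only `r_site` is used).
#' @return `count` x 3 matrix of positions with attributes `seed`, `r_c`.
#' @export
pack_crowders <- function(count, r_c, L_box, seed = 1L, existing_sites = NULL,
                          clearance = NULL, delta = 1e-6,
                          params = interaction_params()) {
  if (count == 0) {
    out <- matrix(numeric(0), ncol = 3)
    attr(out, "seed") <- seed; attr(out, "r_c") <- r_c
    return(out)
  }
  if (is.null(existing_sites)) existing_sites <- matrix(numeric(0), ncol = 3)
  if (is.null(clearance)) clearance <- r_c + params$r_site
  res <- cpp_hs_pack(as.integer(count), r_c, L_box, as.integer(seed),
                     as.matrix(existing_sites), clearance, delta)
  if (!isTRUE(res$ok))
    abort(sprintf("infeasible packing: could not place %d crowders of radius %.2f in a box of %.2f nm",
                  count, r_c, L_box), class = "crowdna_packing_error")
  out <- res$pos
  attr(out, "seed") <- seed; attr(out, "r_c") <- r_c
  out
}

#' Add crowders to a configuration at a target volume fraction
#'
#' @param conf a `cg_configuration`.
#' @param topo the matching `cg_topology` (for site clearance).
#' @param phi target excluded volume fraction.
#' @param r_c crowder radius (nm).
#' @param seed packing seed.
#' @param params interaction parameters.
#' @return the configuration with crowders added and `phi`, `rc`, `seed`
#'   metadata set.
#' @export
add_crowders <- function(conf, topo, phi, r_c = conf$rc, seed = 1L,
                         params = interaction_params()) {
  cnt <- crowders_for_phi(phi, r_c, conf$L)
  sites <- rbind(conf$pos - params$d_back * conf$e1,
                 conf$pos + params$d_base * conf$e1)
  sites <- sites - conf$L * floor(sites / conf$L)
  cpos <- pack_crowders(cnt$count, r_c, conf$L, seed = seed,
                        existing_sites = sites,
                        clearance = (r_c + params$r_site) * 2^(1 / 6),
                        params = params)
  conf$cpos <- cpos
  conf$rc <- r_c
  conf$phi <- phi
  conf$seed <- seed
  conf
}

#' Crowder pair potential
#'
#' WCA form: Lennard-Jones truncated at its minimum `2^(1/6) sigma` and
#' shifted to zero there; purely repulsive, continuous, and monotone
#' decreasing below the cutoff. This is the excluded-volume interaction used
#' for crowder-crowder (with `sigma = 2 r_c`) and crowder-nucleotide (with
#' `sigma = r_c + r_site`) pairs.
#'
#' @param d centre-centre distance(s), nm; must be positive.
#' @param sigma WCA diameter (nm).
#' @param eps_exc energy scale.
#' @return energy (same length as `d`).
#' @examples
#' crowder_pair_energy(1.7, sigma = 1.7, eps_exc = 2) # = eps_exc
#' @export
crowder_pair_energy <- function(d, sigma, eps_exc = 2) {
  if (any(d <= 0)) abort("infinite overlap: distance must be positive",
                         class = "crowdna_overlap_error")
  cutoff <- sigma * 2^(1 / 6)
  s6 <- (sigma / d)^6
  ifelse(d >= cutoff, 0, 4 * eps_exc * (s6^2 - s6) + eps_exc)
}
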