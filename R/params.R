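#' Interaction parameters for the coarse-grained model
#'
#' Assembles the full parameter set of the coarse-grained potential: FENE
#' backbone springs between consecutive backbone sites, Morse-type radial
#' wells with squared-cosine angular modulation for stacking (sequential
#' bases) and hydrogen bonding (native pairs only), and purely repulsive
#' truncated-and-shifted Lennard-Jones (WCA) excluded volume for everything
#' else, including the crowder spheres. All radial wells are truncated and
#' shifted so that each potential is continuous at its cutoff, and the Morse
#' wells are renormalised so their minima are exactly `-eps_hb` / `-eps_st`.
#'
#' Units: lengths in nm, energies in units of \eqn{k_B T_0} (\eqn{T_0} =
#' 300 K), temperatures in kelvin.
#'
#' The defaults are calibrated so that the crowder-free 8-mer duplex melts
#' two-state between 300 K and 360 K in its default box; this calibration is
#' enforced by the test suite rather than tuned to any particular published
#' melting temperature.
#'
#' @param eps_hb hydrogen-bond well depth (averaged model: identical for all
#'   native pairs).
#' @param eps_st stacking well depth.
#' @param a_hb,d0_hb,rc_hb Morse steepness (1/nm), minimum position (nm) and
#'   cutoff (nm) of the hydrogen-bonding well.
#' @param a_st,d0_st,rc_st same for the stacking well.
#' @param fene_k,fene_r0,fene_dr FENE spring constant (energy/nm^2),
#'   equilibrium backbone separation (nm) and maximum extension (nm).
#' @param sig_bb,sig_bs,sig_ss WCA diameters for backbone-backbone,
#'   backbone-base and base-base site pairs (nm).
#' @param eps_exc WCA energy scale for DNA site pairs.
#' @param r_site effective site radius used in the crowder-nucleotide WCA
#'   diameter `r_c + r_site` (additive radii).
#' @param eps_crowd WCA energy scale for crowder interactions.
#' @param d_back,d_base displacement of the backbone and base interaction
#'   sites from the nucleotide centre along its base vector (nm).
#' @param bp_frac a native pair counts as formed when its hydrogen-bond
#'   energy is below `-bp_frac * eps_hb`.
#' @return an object of class `cg_params` (a named list).
#' @examples
#' p <- interaction_params()
#' p$eps_hb
#' @export
interaction_params <- function(eps_hb = 9.5, eps_st = 2.0,
                               a_hb = 5.0, d0_hb = 0.40, rc_hb = 0.85,
                               a_st = 6.0, d0_st = 0.60, rc_st = 1.20,
                               fene_k = 60, fene_r0 = 0.64, fene_dr = 0.25,
                               sig_bb = 0.60, sig_bs = 0.50, sig_ss = 0.40,
                               eps_exc = 2.0, r_site = 0.30, eps_crowd = 2.0,
                               d_back = 0.40, d_base = 0.40, bp_frac = 0.1) {
  p <- list(eps_hb = eps_hb, eps_st = eps_st,
            a_hb = a_hb, d0_hb = d0_hb, rc_hb = rc_hb,
            a_st = a_st, d0_st = d0_st, rc_st = rc_st,
            fene_k = fene_k, fene_r0 = fene_r0, fene_dr = fene_dr,
            sig_bb = sig_bb, sig_bs = sig_bs, sig_ss = sig_ss,
            eps_exc = eps_exc, r_site = r_site, eps_crowd = eps_crowd,
            d_back = d_back, d_base = d_base, bp_frac = bp_frac)
  eps <- c(eps_hb, eps_st, eps_exc, eps_crowd)
  if (any(eps < 0)) abort("all energy scales must be non-negative")
  cuts <- c(rc_hb, rc_st)
  if (any(cuts <= 0)) abort("cutoffs must be positive")
  if (rc_hb <= d0_hb || rc_st <= d0_st)
    abort("Morse cutoffs must exceed the well minimum positions")
  structure(p, class = "cg_params")
}

#' @export
print.cg_params <- function(x, ...) {
  cat("<cg_params> coarse-grained interaction parameters\n")
  cat(sprintf("  eps_hb = %.3g, eps_st = %.3g (kB T0); bp formed below %.2g x eps_hb\n",
              x$eps_hb, x$eps_st, x$bp_frac))
  cat(sprintf("  HB well: d0 = %.2f nm, cutoff %.2f nm; FENE r0 = %.2f +/- %.2f nm\n",
              x$d0_hb, x$rc_hb, x$fene_r0, x$fene_dr))
  invisible(x)
}
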